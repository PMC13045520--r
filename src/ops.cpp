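#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All 4-D feature arrays are column-major [H, W, C, B] (R native layout).
// Directional-field arrays carry channel 1 = dx (column offset),
// channel 2 = dy (row offset), in 0-based pixel-centre coordinates.

static IntegerVector dims_of(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return d;
}

// ---------------------------------------------------------------------------
// 2-D convolution, stride 1, zero padding `pad` (pad = (K-1)/2 gives "same")
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  const int K = wd[0], Co = wd[3];
  if (wd[2] != Ci) stop("conv2d: channel mismatch (%d vs %d)", wd[2], Ci);
  NumericVector y((R_xlen_t)H * W * Co * B);
  y.attr("dim") = IntegerVector::create(H, W, Co, B);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  const size_t HW = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Co; ++co) {
      double* ys = yp + ((size_t)b * Co + co) * HW;
      const double bv = bias[co];
      for (size_t i = 0; i < HW; ++i) ys[i] = bv;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xs = xp + ((size_t)b * Ci + ci) * HW;
        for (int kw = 0; kw < K; ++kw) {
          for (int kh = 0; kh < K; ++kh) {
            const double wv = wp[kh + K * (kw + K * (ci + Ci * co))];
            if (wv == 0.0) continue;
            const int h0 = std::max(0, pad - kh);
            const int h1 = std::min(H - 1, H - 1 + pad - kh);
            const int w0 = std::max(0, pad - kw);
            const int w1 = std::min(W - 1, W - 1 + pad - kw);
            for (int ww = w0; ww <= w1; ++ww) {
              const double* xcol = xs + (size_t)(ww + kw - pad) * H + (kh - pad);
              double* ycol = ys + (size_t)ww * H;
              for (int hh = h0; hh <= h1; ++hh) ycol[hh] += wv * xcol[hh];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int pad) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  const int K = wd[0], Co = wd[3];
  NumericVector dx((R_xlen_t)x.size());
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)w.size());
  dw.attr("dim") = wd;
  NumericVector db(Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  const size_t HW = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Co; ++co) {
      const double* dys = dyp + ((size_t)b * Co + co) * HW;
      double acc_b = 0.0;
      for (size_t i = 0; i < HW; ++i) acc_b += dys[i];
      db[co] += acc_b;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xs = xp + ((size_t)b * Ci + ci) * HW;
        double* dxs = dxp + ((size_t)b * Ci + ci) * HW;
        for (int kw = 0; kw < K; ++kw) {
          for (int kh = 0; kh < K; ++kh) {
            const double wv = wp[kh + K * (kw + K * (ci + Ci * co))];
            double acc_w = 0.0;
            const int h0 = std::max(0, pad - kh);
            const int h1 = std::min(H - 1, H - 1 + pad - kh);
            const int w0 = std::max(0, pad - kw);
            const int w1 = std::min(W - 1, W - 1 + pad - kw);
            for (int ww = w0; ww <= w1; ++ww) {
              const double* xcol = xs + (size_t)(ww + kw - pad) * H + (kh - pad);
              double* dxcol = dxs + (size_t)(ww + kw - pad) * H + (kh - pad);
              const double* dycol = dys + (size_t)ww * H;
              for (int hh = h0; hh <= h1; ++hh) {
                acc_w += xcol[hh] * dycol[hh];
                dxcol[hh] += wv * dycol[hh];
              }
            }
            dwp[kh + K * (kw + K * (ci + Ci * co))] += acc_w;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2 (ties go to the first window element scanned,
// column-major within the window, for determinism)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even (got %dx%d)", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((size_t)b * C + c) * HW;
      double* ys = yp + ((size_t)b * C + c) * HWo;
      int* is = ip + ((size_t)b * C + c) * HWo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int best = 2 * ho + H * (2 * wo);
          double bv = xs[best];
          const int cand[3] = {2 * ho + 1 + H * (2 * wo),
                               2 * ho + H * (2 * wo + 1),
                               2 * ho + 1 + H * (2 * wo + 1)};
          for (int k = 0; k < 3; ++k) {
            if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
          }
          ys[ho + Ho * wo] = bv;
          is[ho + Ho * wo] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               int H, int W) {
  IntegerVector yd = dims_of(dy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* dys = dyp + ((size_t)b * C + c) * HWo;
      const int* is = ip + ((size_t)b * C + c) * HWo;
      double* dxs = dxp + ((size_t)b * C + c) * HW;
      for (size_t i = 0; i < HWo; ++i) dxs[is[i]] += dys[i];
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Bilinear resize (half-pixel-centre mapping, edge clamped)
// ---------------------------------------------------------------------------

static void bilinear_coeffs(int n_in, int n_out, std::vector<int>& i0,
                            std::vector<int>& i1, std::vector<double>& f) {
  i0.resize(n_out); i1.resize(n_out); f.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int a = (int)std::floor(s);
    if (a > n_in - 2) a = std::max(0, n_in - 2);
    i0[i] = a;
    i1[i] = (n_in > 1) ? a + 1 : a;
    f[i] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector resize_bilinear_fwd_cpp(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> fr, fc;
  bilinear_coeffs(H, Ho, r0, r1, fr);
  bilinear_coeffs(W, Wo, c0, c1, fc);
  NumericVector y((R_xlen_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((size_t)b * C + c) * HW;
      double* ys = yp + ((size_t)b * C + c) * HWo;
      for (int wo = 0; wo < Wo; ++wo) {
        const double g = fc[wo];
        const size_t ca = (size_t)c0[wo] * H, cb = (size_t)c1[wo] * H;
        for (int ho = 0; ho < Ho; ++ho) {
          const double fh = fr[ho];
          const double top = (1 - g) * xs[r0[ho] + ca] + g * xs[r0[ho] + cb];
          const double bot = (1 - g) * xs[r1[ho] + ca] + g * xs[r1[ho] + cb];
          ys[ho + (size_t)Ho * wo] = (1 - fh) * top + fh * bot;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bwd_cpp(NumericVector dy, int H, int W) {
  IntegerVector yd = dims_of(dy);
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> fr, fc;
  bilinear_coeffs(H, Ho, r0, r1, fr);
  bilinear_coeffs(W, Wo, c0, c1, fc);
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* dys = dyp + ((size_t)b * C + c) * HWo;
      double* dxs = dxp + ((size_t)b * C + c) * HW;
      for (int wo = 0; wo < Wo; ++wo) {
        const double g = fc[wo];
        const size_t ca = (size_t)c0[wo] * H, cb = (size_t)c1[wo] * H;
        for (int ho = 0; ho < Ho; ++ho) {
          const double fh = fr[ho];
          const double d = dys[ho + (size_t)Ho * wo];
          dxs[r0[ho] + ca] += (1 - fh) * (1 - g) * d;
          dxs[r0[ho] + cb] += (1 - fh) * g * d;
          dxs[r1[ho] + ca] += fh * (1 - g) * d;
          dxs[r1[ho] + cb] += fh * g * d;
        }
      }
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Bilinear warp along a displacement field: y(r,c) = x(r + dy, c + dx),
// fractional coordinates sampled bilinearly, out-of-grid clamped to border.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector warp_bilinear_fwd_cpp(NumericVector x, NumericVector df) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  const double* dfp = df.begin();
  double* yp = y.begin();
  const size_t HW = (size_t)H * W;
  std::vector<int> R0(HW), R1(HW), C0(HW), C1(HW);
  std::vector<double> FR(HW), FC(HW);
  for (int b = 0; b < B; ++b) {
    const double* dfx = dfp + (size_t)b * 2 * HW;
    const double* dfy = dfx + HW;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const size_t i = h + (size_t)H * w;
        double sc = w + dfx[i], sr = h + dfy[i];
        if (!std::isfinite(sc)) sc = w;  // NaN/Inf displacement: stay put
        if (!std::isfinite(sr)) sr = h;
        if (sc < 0) sc = 0;
        if (sc > W - 1) sc = W - 1;
        if (sr < 0) sr = 0;
        if (sr > H - 1) sr = H - 1;
        int a = (int)std::floor(sr);
        if (a > H - 2) a = std::max(0, H - 2);
        int cA = (int)std::floor(sc);
        if (cA > W - 2) cA = std::max(0, W - 2);
        R0[i] = a; R1[i] = (H > 1) ? a + 1 : a; FR[i] = sr - a;
        C0[i] = cA; C1[i] = (W > 1) ? cA + 1 : cA; FC[i] = sc - cA;
      }
    }
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((size_t)b * C + c) * HW;
      double* ys = yp + ((size_t)b * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        const double fr = FR[i], fc = FC[i];
        const size_t ca = (size_t)C0[i] * H, cb = (size_t)C1[i] * H;
        const double top = (1 - fc) * xs[R0[i] + ca] + fc * xs[R0[i] + cb];
        const double bot = (1 - fc) * xs[R1[i] + ca] + fc * xs[R1[i] + cb];
        ys[i] = (1 - fr) * top + fr * bot;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List warp_bilinear_bwd_cpp(NumericVector x, NumericVector df,
                           NumericVector dy) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector dx((R_xlen_t)x.size());
  dx.attr("dim") = xd;
  NumericVector ddf((R_xlen_t)df.size());
  ddf.attr("dim") = df.attr("dim");
  const double* xp = x.begin();
  const double* dfp = df.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* ddfp = ddf.begin();
  const size_t HW = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    const double* dfx = dfp + (size_t)b * 2 * HW;
    const double* dfy = dfx + HW;
    double* ddfx = ddfp + (size_t)b * 2 * HW;
    double* ddfy = ddfx + HW;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const size_t i = h + (size_t)H * w;
        double sc = w + dfx[i], sr = h + dfy[i];
        if (!std::isfinite(sc)) sc = w;
        if (!std::isfinite(sr)) sr = h;
        const bool clc = (sc <= 0.0) || (sc >= W - 1);
        const bool clr = (sr <= 0.0) || (sr >= H - 1);
        if (sc < 0) sc = 0;
        if (sc > W - 1) sc = W - 1;
        if (sr < 0) sr = 0;
        if (sr > H - 1) sr = H - 1;
        int r0 = (int)std::floor(sr);
        if (r0 > H - 2) r0 = std::max(0, H - 2);
        int c0 = (int)std::floor(sc);
        if (c0 > W - 2) c0 = std::max(0, W - 2);
        const int r1 = (H > 1) ? r0 + 1 : r0;
        const int c1 = (W > 1) ? c0 + 1 : c0;
        const double fr = sr - r0, fc = sc - c0;
        double gx = 0.0, gy = 0.0;
        for (int c = 0; c < C; ++c) {
          const double* xs = xp + ((size_t)b * C + c) * HW;
          double* dxs = dxp + ((size_t)b * C + c) * HW;
          const double d = dyp[((size_t)b * C + c) * HW + i];
          if (d == 0.0) continue;
          const size_t ca = (size_t)c0 * H, cb = (size_t)c1 * H;
          dxs[r0 + ca] += (1 - fr) * (1 - fc) * d;
          dxs[r0 + cb] += (1 - fr) * fc * d;
          dxs[r1 + ca] += fr * (1 - fc) * d;
          dxs[r1 + cb] += fr * fc * d;
          gx += d * ((1 - fr) * (xs[r0 + cb] - xs[r0 + ca]) +
                     fr * (xs[r1 + cb] - xs[r1 + ca]));
          gy += d * ((1 - fc) * (xs[r1 + ca] - xs[r0 + ca]) +
                     fc * (xs[r1 + cb] - xs[r0 + cb]));
        }
        if (!clc) ddfx[i] = gx;
        if (!clr) ddfy[i] = gy;
      }
    }
  }
  return List::create(_["dx"] = dx, _["ddf"] = ddf);
}

// ---------------------------------------------------------------------------
// Boundary pixels and ground-truth directional fields
// ---------------------------------------------------------------------------

static bool is_boundary_px(const IntegerMatrix& mask, int r, int c,
                           int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int lab = mask(r, c);
  static const int d4r[4] = {-1, 1, 0, 0};
  static const int d4c[4] = {0, 0, -1, 1};
  static const int d8r[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int d8c[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 8) ? d8r : d4r;
  const int* dc = (connectivity == 8) ? d8c : d4c;
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int k = 0; k < nn; ++k) {
    const int rr = r + dr[k], cc = c + dc[k];
    if (rr < 0 || rr >= H || cc < 0 || cc >= W) return true;  // grid edge = background
    if (mask(rr, cc) != lab) return true;
  }
  return false;
}

// [[Rcpp::export]]
LogicalMatrix boundary_cpp(IntegerMatrix mask, int label, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (mask(r, c) == label)
        out(r, c) = is_boundary_px(mask, r, c, connectivity);
  return out;
}

// Nearest boundary pixel per foreground pixel; ties broken by row-major
// smallest boundary pixel (the boundary list is scanned in row-major order
// with strict improvement, so the first minimum wins).
static void fill_df_for_pixels(const std::vector<int>& fr,
                               const std::vector<int>& fc,
                               const std::vector<int>& br,
                               const std::vector<int>& bc,
                               NumericVector& df, int H) {
  const size_t HW = df.size() / 2;
  double* dxs = df.begin();
  double* dys = dxs + HW;
  for (size_t i = 0; i < fr.size(); ++i) {
    const int pr = fr[i], pc = fc[i];
    long best = -1;
    long bestd = -1;
    for (size_t j = 0; j < br.size(); ++j) {
      const long dr = pr - br[j], dc = pc - bc[j];
      const long d2 = dr * dr + dc * dc;
      if (best < 0 || d2 < bestd) { best = (long)j; bestd = d2; }
    }
    if (best >= 0 && bestd > 0) {
      const double dr = pr - br[best], dc = pc - bc[best];
      const double nrm = std::sqrt(dr * dr + dc * dc);
      const size_t idx = (size_t)pr + (size_t)H * pc;
      dxs[idx] = dc / nrm;
      dys[idx] = dr / nrm;
    }
  }
}

// [[Rcpp::export]]
NumericVector df_from_mask_cpp(IntegerMatrix mask, bool per_class,
                               int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericVector df((R_xlen_t)H * W * 2);
  df.attr("dim") = IntegerVector::create(H, W, 2);
  int maxlab = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (mask(r, c) > maxlab) maxlab = mask(r, c);
  if (maxlab == 0) return df;
  // boundary flags (each foreground pixel vs its own class)
  LogicalMatrix isb(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (mask(r, c) > 0) isb(r, c) = is_boundary_px(mask, r, c, connectivity);
  if (per_class) {
    for (int lab = 1; lab <= maxlab; ++lab) {
      std::vector<int> br, bc, fr, fc;
      for (int r = 0; r < H; ++r)      // row-major collection for tie rule
        for (int c = 0; c < W; ++c)
          if (mask(r, c) == lab) {
            if (isb(r, c)) { br.push_back(r); bc.push_back(c); }
            else { fr.push_back(r); fc.push_back(c); }
          }
      fill_df_for_pixels(fr, fc, br, bc, df, H);
    }
  } else {
    std::vector<int> br, bc, fr, fc;
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        if (mask(r, c) > 0) {
          if (isb(r, c)) { br.push_back(r); bc.push_back(c); }
          else { fr.push_back(r); fc.push_back(c); }
        }
    fill_df_for_pixels(fr, fc, br, bc, df, H);
  }
  return df;
}

// ---------------------------------------------------------------------------
// Symmetric Hausdorff distance between two point sets (rows = points)
// ---------------------------------------------------------------------------

static double directed_hd(const NumericMatrix& A, const NumericMatrix& B) {
  double worst = 0.0;
  for (int i = 0; i < A.nrow(); ++i) {
    double best = R_PosInf;
    for (int j = 0; j < B.nrow(); ++j) {
      const double dr = A(i, 0) - B(j, 0), dc = A(i, 1) - B(j, 1);
      const double d2 = dr * dr + dc * dc;
      if (d2 < best) best = d2;
      if (best <= worst) break;  // cannot raise the max
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}

// [[Rcpp::export]]
double hausdorff_cpp(NumericMatrix A, NumericMatrix B) {
  if (A.nrow() == 0 || B.nrow() == 0) return NA_REAL;
  return std::max(directed_hd(A, B), directed_hd(B, A));
}
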