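## Internal neural-network primitives with hand-written backward passes.
##
## Feature maps are column-major arrays [H, W, C, B]; token stacks are
## arrays [N, D, B]. Every *_fwd returns list(y, cache); every *_bwd takes
## the upstream gradient plus the cache and returns the input gradient and
## per-parameter gradients. No autodiff framework exists in this stack, so
## the chain rule is composed explicitly in model_forward/model_backward.

.truncnorm <- function(n, sd = 0.02) {
  z <- rnorm(n)
  pmin(pmax(z, -2), 2) * sd
}

.he_conv <- function(K, ci, co) {
  array(rnorm(K * K * ci * co, sd = sqrt(2 / (K * K * ci))), c(K, K, ci, co))
}

.as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) dim(x) <- c(d, 1L)
  x
}

# ---- convolution ----------------------------------------------------------
#
# Two routes with identical results: an im2col + BLAS matmul path (fast,
# memory-hungry) and a scalar C++ loop used when the unrolled patch matrix
# would exceed .IM2COL_LIMIT bytes.

.IM2COL_LIMIT <- 512 * 1024^2

# (H*W*B, K*K*Ci) patch matrix; column order (kh, kw, ci), kh fastest,
# matching the column-major layout of the [K,K,Ci,Co] weight array.
.im2col <- function(x, K, pad) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; Ci <- d[3]; B <- d[4]
  if (K == 1L) return(matrix(aperm(x, c(1, 2, 4, 3)), ncol = Ci))
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, B, Ci))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- aperm(x, c(1, 2, 4, 3))
  M <- matrix(0, H * W * B, K * K * Ci)
  for (ci in seq_len(Ci)) for (kw in seq_len(K)) for (kh in seq_len(K)) {
    ko <- (ci - 1L) * K * K + (kw - 1L) * K + kh
    M[, ko] <- xp[kh:(kh + H - 1L), kw:(kw + W - 1L), , ci]
  }
  M
}

# scatter-add transpose of .im2col
.col2im <- function(dM, d, K, pad) {
  H <- d[1]; W <- d[2]; Ci <- d[3]; B <- d[4]
  if (K == 1L) return(aperm(array(dM, c(H, W, B, Ci)), c(1, 2, 4, 3)))
  dxp <- array(0, c(H + 2 * pad, W + 2 * pad, B, Ci))
  for (ci in seq_len(Ci)) for (kw in seq_len(K)) for (kh in seq_len(K)) {
    ko <- (ci - 1L) * K * K + (kw - 1L) * K + kh
    sub <- dxp[kh:(kh + H - 1L), kw:(kw + W - 1L), , ci, drop = FALSE]
    dxp[kh:(kh + H - 1L), kw:(kw + W - 1L), , ci] <-
      sub + array(dM[, ko], dim(sub))
  }
  aperm(dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE],
        c(1, 2, 4, 3))
}

conv_fwd <- function(x, W, b) {
  K <- dim(W)[1]
  pad <- (K - 1L) %/% 2L
  d <- dim(x)
  big <- prod(d[1], d[2], d[4]) * K * K * d[3] * 8 > .IM2COL_LIMIT
  if (big) {
    y <- conv2d_fwd_cpp(x, W, b, pad)
    return(list(y = y, cache = list(x = x, W = W, pad = pad, big = TRUE)))
  }
  M <- .im2col(x, K, pad)
  Co <- dim(W)[4]
  ym <- M %*% matrix(W, ncol = Co)
  ym <- ym + matrix(b, nrow(ym), Co, byrow = TRUE)
  y <- aperm(array(ym, c(d[1], d[2], d[4], Co)), c(1, 2, 4, 3))
  list(y = y, cache = list(M = M, W = W, d = d, pad = pad, big = FALSE))
}

conv_bwd <- function(dy, cache) {
  if (isTRUE(cache$big)) {
    g <- conv2d_bwd_cpp(cache$x, cache$W, dy, cache$pad)
    return(list(dx = g$dx, dW = g$dw, db = g$db))
  }
  W <- cache$W
  K <- dim(W)[1]
  Co <- dim(W)[4]
  d <- cache$d
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = Co)
  Wm <- matrix(W, ncol = Co)
  dW <- array(crossprod(cache$M, dym), dim(W))
  db <- colSums(dym)
  dx <- .col2im(dym %*% t(Wm), d, K, cache$pad)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization --------------------------------------------------

.chan_bcast <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
}

bn_fwd <- function(x, gamma, beta, rmean, rvar, train,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  if (train) {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
    mu <- colMeans(xm)
    v <- pmax(colMeans(xm * xm) - mu^2, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - .chan_bcast(mu, d)) * .chan_bcast(invstd, d)
  y <- xhat * .chan_bcast(gamma, d) + .chan_bcast(beta, d)
  list(y = y, rmean = rmean, rvar = rvar,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    train = train, d = d))
}

bn_bwd <- function(dy, cache) {
  d <- cache$d
  m <- d[1] * d[2] * d[4]
  xhat <- cache$xhat
  sum_c <- function(a) colSums(matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3]))
  dgamma <- sum_c(dy * xhat)
  dbeta <- sum_c(dy)
  dxhat <- dy * .chan_bcast(cache$gamma, d)
  if (cache$train) {
    s1 <- sum_c(dxhat)
    s2 <- sum_c(dxhat * xhat)
    dx <- .chan_bcast(cache$invstd / m, d) *
      (m * dxhat - .chan_bcast(s1, d) - xhat * .chan_bcast(s2, d))
  } else {
    dx <- dxhat * .chan_bcast(cache$invstd, d)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations ----------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

gelu_fwd <- function(x) list(y = x * pnorm(x), cache = x)
gelu_bwd <- function(dy, cache) dy * (pnorm(cache) + cache * dnorm(cache))

# ---- pooling / resampling (C++ backed) ------------------------------------

pool_fwd <- function(x) {
  r <- maxpool2_fwd_cpp(x)
  list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}
pool_bwd <- function(dy, cache) maxpool2_bwd_cpp(dy, cache$idx, cache$H, cache$W)

resize_fwd <- function(x, Ho, Wo) {
  list(y = resize_bilinear_fwd_cpp(x, Ho, Wo),
       cache = list(H = dim(x)[1], W = dim(x)[2]))
}
resize_bwd <- function(dy, cache) resize_bilinear_bwd_cpp(dy, cache$H, cache$W)

warp_fwd <- function(x, df) {
  list(y = warp_bilinear_fwd_cpp(x, df), cache = list(x = x, df = df))
}
warp_bwd <- function(dy, cache) warp_bilinear_bwd_cpp(cache$x, cache$df, dy)

# ---- token ops ------------------------------------------------------------

# [h,w,C,B] -> tokens [N, P^2*C, B]; patch grid scanned row-major
# (patch-column fastest), features within a patch column-major (row, col,
# channel) -- the inverse rearrangements below must match exactly.
patchify_fwd <- function(x, P) {
  d <- dim(x)
  hp <- d[1] %/% P
  wp <- d[2] %/% P
  if (hp * P != d[1] || wp * P != d[2])
    stop(sprintf("spatial dims %dx%d not divisible by patch size %d",
                 d[1], d[2], P))
  a6 <- array(x, c(P, hp, P, wp, d[3], d[4]))
  ap <- aperm(a6, c(4, 2, 1, 3, 5, 6))
  tok <- array(ap, c(wp * hp, P * P * d[3], d[4]))
  list(y = tok, cache = list(d = d, P = P, hp = hp, wp = wp))
}

patchify_bwd <- function(dtok, cache) {
  d <- cache$d; P <- cache$P
  ap <- array(dtok, c(cache$wp, cache$hp, P, P, d[3], d[4]))
  a6 <- aperm(ap, c(3, 2, 4, 1, 5, 6))
  array(a6, d)
}

# tokens [N,D,B] -> grid [hp,wp,D,B] (row-major token order)
tok2grid <- function(tok, hp, wp) {
  d <- dim(tok)
  aperm(array(tok, c(wp, hp, d[2], d[3])), c(2, 1, 3, 4))
}
grid2tok <- function(grid) {
  d <- dim(grid)
  array(aperm(grid, c(2, 1, 3, 4)), c(d[1] * d[2], d[3], d[4]))
}

.tok_mat <- function(tok) {
  d <- dim(tok)
  matrix(aperm(tok, c(1, 3, 2)), ncol = d[2])  # (N*B, D)
}
.mat_tok <- function(m, N, B) {
  aperm(array(m, c(N, B, ncol(m))), c(1, 3, 2))
}

lin_fwd <- function(tok, W, b) {
  d <- dim(tok)
  tm <- .tok_mat(tok)
  ym <- tm %*% W
  ym <- ym + matrix(b, nrow(ym), length(b), byrow = TRUE)
  list(y = .mat_tok(ym, d[1], d[3]), cache = list(tm = tm, W = W, d = d))
}

lin_bwd <- function(dy, cache) {
  dym <- .tok_mat(dy)
  list(dx = .mat_tok(dym %*% t(cache$W), cache$d[1], cache$d[3]),
       dW = crossprod(cache$tm, dym), db = colSums(dym))
}

ln_fwd <- function(tok, gamma, beta, eps = 1e-6) {
  d <- dim(tok)
  tm <- .tok_mat(tok)
  mu <- rowMeans(tm)
  v <- rowMeans(tm * tm) - mu^2
  invstd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- (tm - mu) * invstd
  ym <- xhat * matrix(gamma, nrow(tm), ncol(tm), byrow = TRUE) +
    matrix(beta, nrow(tm), ncol(tm), byrow = TRUE)
  list(y = .mat_tok(ym, d[1], d[3]),
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d))
}

ln_bwd <- function(dy, cache) {
  d <- cache$d
  dym <- .tok_mat(dy)
  xhat <- cache$xhat
  Dd <- ncol(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * matrix(cache$gamma, nrow(dym), Dd, byrow = TRUE)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dxm <- (cache$invstd / Dd) * (Dd * dxhat - s1 - xhat * s2)
  list(dx = .mat_tok(dxm, d[1], d[3]), dgamma = dgamma, dbeta = dbeta)
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

msa_fwd <- function(tok, p, heads) {
  d <- dim(tok)
  N <- d[1]; D <- d[2]; B <- d[3]
  dh <- D %/% heads
  Y <- array(0, d)
  cc <- vector("list", B)
  for (b in seq_len(B)) {
    X <- tok[, , b, drop = FALSE]; dim(X) <- c(N, D)
    Q <- X %*% p$Wq + matrix(p$bq, N, D, byrow = TRUE)
    K <- X %*% p$Wk + matrix(p$bk, N, D, byrow = TRUE)
    V <- X %*% p$Wv + matrix(p$bv, N, D, byrow = TRUE)
    O <- matrix(0, N, D)
    A <- vector("list", heads)
    for (h in seq_len(heads)) {
      ix <- ((h - 1) * dh + 1):(h * dh)
      Ah <- .softmax_rows(Q[, ix, drop = FALSE] %*%
                            t(K[, ix, drop = FALSE]) / sqrt(dh))
      O[, ix] <- Ah %*% V[, ix, drop = FALSE]
      A[[h]] <- Ah
    }
    Y[, , b] <- O %*% p$Wo + matrix(p$bo, N, D, byrow = TRUE)
    cc[[b]] <- list(X = X, Q = Q, K = K, V = V, O = O, A = A)
  }
  list(y = Y, cache = list(cc = cc, heads = heads, dh = dh, d = d))
}

msa_bwd <- function(dy, cache, p) {
  d <- cache$d
  N <- d[1]; D <- d[2]; B <- d[3]
  heads <- cache$heads; dh <- cache$dh
  dX <- array(0, d)
  g <- list(Wq = 0 * p$Wq, Wk = 0 * p$Wk, Wv = 0 * p$Wv, Wo = 0 * p$Wo,
            bq = 0 * p$bq, bk = 0 * p$bk, bv = 0 * p$bv, bo = 0 * p$bo)
  for (b in seq_len(B)) {
    cb <- cache$cc[[b]]
    dYb <- dy[, , b, drop = FALSE]; dim(dYb) <- c(N, D)
    g$Wo <- g$Wo + crossprod(cb$O, dYb)
    g$bo <- g$bo + colSums(dYb)
    dO <- dYb %*% t(p$Wo)
    dQ <- matrix(0, N, D); dK <- matrix(0, N, D); dV <- matrix(0, N, D)
    for (h in seq_len(heads)) {
      ix <- ((h - 1) * dh + 1):(h * dh)
      Ah <- cb$A[[h]]
      dOh <- dO[, ix, drop = FALSE]
      dAh <- dOh %*% t(cb$V[, ix, drop = FALSE])
      dV[, ix] <- crossprod(Ah, dOh)
      dZ <- Ah * (dAh - rowSums(dAh * Ah))
      dQ[, ix] <- dZ %*% cb$K[, ix, drop = FALSE] / sqrt(dh)
      dK[, ix] <- crossprod(dZ, cb$Q[, ix, drop = FALSE]) / sqrt(dh)
    }
    g$Wq <- g$Wq + crossprod(cb$X, dQ); g$bq <- g$bq + colSums(dQ)
    g$Wk <- g$Wk + crossprod(cb$X, dK); g$bk <- g$bk + colSums(dK)
    g$Wv <- g$Wv + crossprod(cb$X, dV); g$bv <- g$bv + colSums(dV)
    dX[, , b] <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  list(dx = dX, grads = g)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gnm
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, st = st)
}
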