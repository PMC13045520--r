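## Training losses (Dice, directional-field supervision) and evaluation
## metrics (per-class Dice coefficient, symmetric Hausdorff distance).

.one_hot <- function(grid, C) {
  H <- nrow(grid); W <- ncol(grid)
  oh <- array(0, c(H, W, C))
  v <- as.vector(grid)
  oh[cbind(rep(seq_len(H), W), rep(seq_len(W), each = H), v + 1L)] <- 1
  oh
}

#' Soft Dice loss over foreground classes
#'
#' 1 minus the mean over foreground classes of
#' (2 sum(p g) + eps) / (sum(p) + sum(g) + eps), with eps = 1e-5; the
#' target is one-hot encoded internally. Channel 1 (background) does not
#' enter the mean.
#'
#' @param probabilities H x W x C array of per-pixel class probabilities
#'   (each pixel's channel vector sums to 1).
#' @param target a [LabelMask-class] with the same spatial dims.
#' @param eps smoothing constant.
#' @return scalar loss in [0, 1].
#' @export
diceLoss <- function(probabilities, target, eps = 1e-5) {
  stopifnot(is(target, "LabelMask"))
  d <- dim(probabilities)
  g <- maskGrid(target)
  if (!all(d[1:2] == dim(g))) stop("probability/target shape mismatch")
  C <- d[3]
  oh <- .one_hot(g, C)
  dice <- vapply(2:C, function(c) {
    pc <- probabilities[, , c]; gc <- oh[, , c]
    (2 * sum(pc * gc) + eps) / (sum(pc) + sum(gc) + eps)
  }, numeric(1))
  1 - mean(dice)
}

# batched dice loss with gradient wrt logits; masks: list of LabelMask
.dice_loss_grad <- function(logits, masks, eps = 1e-5) {
  d <- dim(logits)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  # logits layout is [H,W,C,B]; rearrange to (H*W*B, C) pixel rows
  m <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = C)
  m <- m - apply(m, 1, max)
  e <- exp(m)
  pm <- e / rowSums(e)
  ohm <- matrix(0, nrow(pm), C)
  for (b in seq_len(B)) {
    v <- as.vector(maskGrid(masks[[b]]))
    rows <- (b - 1L) * H * W + seq_len(H * W)
    ohm[cbind(rows, v + 1L)] <- 1
  }
  nf <- C - 1L
  dLdp <- matrix(0, nrow(pm), C)
  dice <- numeric(nf)
  for (c in 2:C) {
    pc <- pm[, c]; gc <- ohm[, c]
    num <- 2 * sum(pc * gc) + eps
    den <- sum(pc) + sum(gc) + eps
    dice[c - 1L] <- num / den
    dLdp[, c] <- -(1 / nf) * (2 * gc * den - num) / den^2
  }
  # softmax backward
  dlog <- pm * (dLdp - rowSums(dLdp * pm))
  dlogits <- aperm(array(dlog, c(H, W, B, C)), c(1, 2, 4, 3))
  list(loss = 1 - mean(dice), dlogits = dlogits,
       meanDice = mean(dice))
}

#' Directional-field supervision loss
#'
#' Mean squared error between a predicted 2-channel field and the ground
#' truth, restricted to foreground pixels: the per-pixel squared error is
#' (pdx-gdx)^2 + (pdy-gdy)^2 and the mean runs over foreground pixels, so
#' an all-zero prediction against unit vectors scores exactly 1.
#'
#' @param predicted H x W x 2 array (the DF head output).
#' @param gt a [DirectionalField-class] or H x W x 2 array at the same
#'   resolution (down-sample the full-resolution GT by nearest-index
#'   first; see [decimateDF()]).
#' @param foreground logical H x W matrix of foreground pixels; by default
#'   pixels where the GT field is non-zero or that sit on a boundary are
#'   not distinguished, so provide the down-sampled foreground mask
#'   explicitly for faithful masking.
#' @return scalar loss (0 when no foreground pixel exists).
#' @export
dfLoss <- function(predicted, gt, foreground = NULL) {
  gv <- if (is(gt, "DirectionalField")) dfVectors(gt) else gt
  if (!all(dim(predicted) == dim(gv))) stop("field shape mismatch")
  if (is.null(foreground))
    foreground <- (gv[, , 1]^2 + gv[, , 2]^2) > 0
  n <- sum(foreground)
  if (n == 0) return(0)
  se <- (predicted[, , 1] - gv[, , 1])^2 + (predicted[, , 2] - gv[, , 2])^2
  sum(se[foreground]) / n
}

# batched df loss + gradient; pred [h,w,2,B], gt [h,w,2,B], fg [h,w,B]
.df_loss_grad <- function(pred, gt, fg) {
  n <- sum(fg)
  if (n == 0) return(list(loss = 0, dpred = pred * 0))
  d <- dim(pred)
  fg4 <- array(0, d)
  fg4[, , 1, ] <- fg
  fg4[, , 2, ] <- fg
  diff <- (pred - gt) * fg4
  list(loss = sum(diff^2) / n, dpred = 2 * diff / n)
}

#' Down-sample a directional field by nearest-index decimation
#' @param field a [DirectionalField-class] or H x W x 2 array.
#' @param factor integer decimation factor s; rows/cols 1, 1+s, 1+2s, ...
#'   are kept.
#' @return decimated array (H/s) x (W/s) x 2.
#' @export
decimateDF <- function(field, factor) {
  v <- if (is(field, "DirectionalField")) dfVectors(field) else field
  if (factor == 1) return(v)
  ri <- seq(1, dim(v)[1], by = factor)
  ci <- seq(1, dim(v)[2], by = factor)
  v[ri, ci, , drop = FALSE]
}

#' Dice coefficient of one class between two masks
#'
#' 2|A n B| / (|A| + |B|) on the binary masks of `label`; defined as 1
#' when the class is absent from both masks.
#'
#' @param pred,gt [LabelMask-class] objects of equal dims.
#' @param label integer class id.
#' @return fraction in [0, 1].
#' @export
diceCoefficient <- function(pred, gt, label) {
  a <- maskGrid(pred) == label
  b <- maskGrid(gt) == label
  if (!all(dim(a) == dim(b))) stop("mask shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Symmetric Hausdorff distance of one class between two masks
#'
#' max(h(A,B), h(B,A)) with h(A,B) = max_a min_b ||a-b||, computed on the
#' boundary pixel sets of `label` (8-connectivity boundaries of the binary
#' class masks), optionally scaled by pixel spacing.
#'
#' @param pred,gt [LabelMask-class] objects of equal dims.
#' @param label integer class id.
#' @param spacing numeric(2) (row, col) scale per pixel; defaults to the
#'   masks' spacing when present, else 1 px.
#' @return distance >= 0, or `NA` when the class is empty on either side
#'   (recorded as missing, never silently 0 or Inf).
#' @export
hausdorffDistance <- function(pred, gt, label, spacing = NULL) {
  if (is.null(spacing)) {
    spacing <- pixelSpacing(gt)
    if (length(spacing) != 2) spacing <- c(1, 1)
  }
  A <- .class_boundary_coords(pred, label)
  B <- .class_boundary_coords(gt, label)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  A <- A * matrix(spacing, nrow(A), 2, byrow = TRUE)
  B <- B * matrix(spacing, nrow(B), 2, byrow = TRUE)
  hausdorff_cpp(A, B)
}

# boundary coordinates of the binary mask of `label` (8-connectivity on
# the binarized grid, so internal class-class interfaces do not count)
.class_boundary_coords <- function(mask, label) {
  g <- maskGrid(mask)
  bin <- matrix(as.integer(g == label), nrow(g), ncol(g))
  hit <- which(boundary_cpp(bin, 1L, 8L), arr.ind = TRUE)
  if (!length(hit)) return(matrix(numeric(0), 0, 2))
  matrix(as.numeric(hit), ncol = 2)
}

#' Per-class segmentation evaluation report
#'
#' Computes the Dice coefficient and Hausdorff distance for every
#' foreground class over one or more frame pairs and appends a mean row
#' (mean over the 6 foreground classes; background is excluded).
#'
#' @param pred,gt a [LabelMask-class] or list of them (paired by position).
#' @param spacing optional numeric(2) pixel spacing; when absent, values
#'   are in px and the report's `units` attribute says so.
#' @return data.frame with columns `class`, `dice`, `hausdorff` and one
#'   row per foreground class plus `"mean"`; attribute `units` is `"mm"`
#'   or `"px"`. Frames where a class is empty on either side contribute
#'   `NA` Hausdorff values, which the mean skips.
#' @export
evaluateMasks <- function(pred, gt, spacing = NULL) {
  if (is(pred, "LabelMask")) pred <- list(pred)
  if (is(gt, "LabelMask")) gt <- list(gt)
  stopifnot(length(pred) == length(gt))
  cn <- classNames(gt[[1]])
  C <- length(cn)
  if (is.null(spacing)) {
    sp <- pixelSpacing(gt[[1]])
    spacing <- if (length(sp) == 2) sp else NULL
  }
  units <- if (is.null(spacing)) "px" else "mm"
  rows <- lapply(seq_len(C - 1L), function(lab) {
    dc <- vapply(seq_along(pred), function(i)
      diceCoefficient(pred[[i]], gt[[i]], lab), numeric(1))
    hd <- vapply(seq_along(pred), function(i)
      hausdorffDistance(pred[[i]], gt[[i]], lab, spacing), numeric(1))
    data.frame(class = cn[lab + 1L], dice = mean(dc),
               hausdorff = if (all(is.na(hd))) NA_real_
                           else mean(hd, na.rm = TRUE))
  })
  rep <- do.call(rbind, rows)
  rep <- rbind(rep, data.frame(class = "mean", dice = mean(rep$dice),
                               hausdorff = if (all(is.na(rep$hausdorff)))
                                 NA_real_
                               else mean(rep$hausdorff, na.rm = TRUE)))
  attr(rep, "units") <- units
  rep
}

#' Write an evaluation report to CSV and/or JSON
#' @param report a data.frame from [evaluateMasks()].
#' @param csv,json optional output paths.
#' @return the report, invisibly.
#' @export
writeEvalReport <- function(report, csv = NULL, json = NULL) {
  units <- attr(report, "units")
  out <- cbind(report, units = units)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(units = units, metrics = report), json,
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
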