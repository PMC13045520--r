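## Progressive refinement decoder configuration and the stateless pieces
## that are meaningful outside a built model: the directional-field head
## (a 1x1 convolution to 2 channels) and feature rectification (iterated
## bilinear resampling of a feature map along a directional field,
## F^k(p) = F^(k-1)(p_x + DF(p)_x, p_y + DF(p)_y), k = 1..N, followed by
## concatenation with F^0 and a 1x1 fusion convolution).

#' Decoder configuration
#'
#' @param stageChannels per-stage output channel counts, deepest first, or
#'   `NULL` to derive defaults at build time (256 for stages without a skip
#'   connection, then 256, 128, 64 for the three skip stages).
#' @param nRefine number of refinement modules (0..4, default 3); they
#'   attach to the shallowest `nRefine` decoder stages, so with one module
#'   the refinement sits at the final (full-resolution) layer and with
#'   three it follows each of the three skip connections.
#' @param rectSteps total rectification steps N (default 6, the speech
#'   configuration).
#' @param numClasses output channels (7 for speech: background + 6).
#' @return A list of class `"DecoderConfig"`.
#' @export
decoderConfig <- function(stageChannels = NULL, nRefine = 3, rectSteps = 6,
                          numClasses = 7) {
  stopifnot(nRefine >= 0, nRefine <= 4, numClasses >= 2)
  if (nRefine >= 1 && rectSteps < 1)
    stop("rectSteps must be >= 1 when refinement modules are present")
  structure(list(stageChannels = if (is.null(stageChannels)) NULL
                                 else as.integer(stageChannels),
                 nRefine = as.integer(nRefine),
                 rectSteps = as.integer(rectSteps),
                 numClasses = as.integer(numClasses)),
            class = "DecoderConfig")
}

#' Speech-configuration decoder (N = 6 steps, 3 refinement modules, 7 classes)
#' @return A `"DecoderConfig"`.
#' @export
speechDecoderConfig <- function() decoderConfig()

#' Desk-scale decoder for tests and smoke runs
#' @return A `"DecoderConfig"` with small stage widths.
#' @export
tinyDecoderConfig <- function()
  decoderConfig(stageChannels = c(32, 32, 24, 16), nRefine = 3,
                rectSteps = 6, numClasses = 7)

#' Directional-field head: pointwise projection to 2 channels
#'
#' @param features numeric array h x w x C (or h x w x C x B).
#' @param W weight array 1 x 1 x C x 2 (or C x 2 matrix).
#' @param b length-2 bias.
#' @return array with the same spatial (and batch) dims and 2 channels.
#' @export
dfHead <- function(features, W, b = c(0, 0)) {
  x <- .as4d(features)
  if (is.matrix(W)) W <- array(W, c(1, 1, nrow(W), ncol(W)))
  y <- conv_fwd(x, W, b)$y
  if (length(dim(features)) <= 3) array(y, dim(y)[1:3]) else y
}

#' Feature rectification along a directional field
#'
#' Iterates F^k(p) = F^(k-1)(p_x + DF(p)_x, p_y + DF(p)_y) for k = 1..N
#' with bilinear sampling at fractional coordinates and border clamping,
#' always reading the displacement from the *initial* field. With
#' `fuseW = NULL` the warped map F^N is returned as-is (the pre-fusion
#' map); otherwise [F^N; F^0] is passed through the 1x1 fusion convolution.
#'
#' @param features numeric array h x w x C (or h x w x C x B), F^0.
#' @param df displacement field h x w x 2 (channels dx, dy) or with batch.
#' @param steps total steps N (>= 0; 0 returns `features`).
#' @param fuseW optional fusion weights 1 x 1 x 2C x Cout.
#' @param fuseB optional fusion bias (length Cout).
#' @return rectified feature array with the input's spatial dims.
#' @export
frfRectify <- function(features, df, steps, fuseW = NULL, fuseB = NULL) {
  if (steps < 0) stop("steps must be >= 0")
  x <- .as4d(features)
  dfx <- .as4d(df)
  if (!all(dim(dfx)[1:2] == dim(x)[1:2]) || dim(dfx)[3] != 2)
    stop("df must be H x W x 2 matching the features' spatial dims")
  Fk <- x
  for (k in seq_len(steps)) Fk <- warp_bilinear_fwd_cpp(Fk, dfx)
  if (!is.null(fuseW)) {
    cat2 <- .cat_channels(Fk, x)
    Fk <- conv_fwd(cat2, fuseW,
                   if (is.null(fuseB)) rep(0, dim(fuseW)[4]) else fuseB)$y
  }
  if (length(dim(features)) <= 3) array(Fk, dim(Fk)[1:3]) else Fk
}

.cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Aggregate refined maps with the decoder output into class logits
#'
#' Each refined map is projected to `numClasses` channels by a 1x1
#' convolution, bilinearly up-sampled to the decoder output's spatial dims
#' and summed with the decoder output's own projection.
#'
#' @param refinedMaps list (possibly empty) of arrays h_i x w_i x C_i.
#' @param decoderOut array H x W x C (the final decoder feature map).
#' @param projections list of length `length(refinedMaps) + 1`: 1x1 weight
#'   arrays for each refined map and, last, for `decoderOut`; each entry a
#'   list(W, b).
#' @return H x W x numClasses logits array.
#' @export
aggregateLogits <- function(refinedMaps, decoderOut, projections) {
  dec <- .as4d(decoderOut)
  ph <- projections[[length(projections)]]
  logits <- conv_fwd(dec, ph$W, ph$b)$y
  H <- dim(dec)[1]; W <- dim(dec)[2]
  for (i in seq_along(refinedMaps)) {
    pm <- projections[[i]]
    r <- conv_fwd(.as4d(refinedMaps[[i]]), pm$W, pm$b)$y
    if (!all(dim(r)[1:2] == c(H, W)))
      r <- resize_bilinear_fwd_cpp(r, H, W)
    logits <- logits + r
  }
  if (length(dim(decoderOut)) <= 3) array(logits, dim(logits)[1:3])
  else logits
}
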