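## Deterministic vocal-tract phantom generator.
##
## The phantom emulates the structure of midsagittal speech MRI series:
## a 7-label layout (background + head with a posterior pharyngeal wall,
## soft palate, jaw, tongue, vocal-tract airway, tooth space) in which the
## soft-palate flap's tip follows a prescribed closure schedule - touching
## the posterior wall on scheduled-closed frames and keeping a >= 2 px air
## gap otherwise - so the generated closure labels and the mask-based
## closure detector agree by construction. Geometry is parametric
## (axis-aligned bands and an ellipse), intensities are per-class base
## levels plus additive Gaussian noise. It makes no claim about MR
## physics: no coil profiles, banding or motion artifacts.

#' Phantom series configuration
#'
#' @param frames number of frames.
#' @param size c(H, W) in pixels (default 64 x 64).
#' @param closureSchedule data.frame with `start`, `end` (0-based,
#'   inclusive, disjoint, within 0..frames-1): frames scheduled closed.
#' @param noiseSigma Gaussian intensity noise s.d. (normalized units).
#' @param seed RNG seed; the same seed reproduces the series bit for bit.
#' @param anteriorAttachment if TRUE the palate is drawn attached
#'   anteriorly to the head (as in real anatomy), so closure detection
#'   then requires a posterior ROI; default FALSE keeps the full-frame ROI
#'   unambiguous.
#' @return list of class `"PhantomConfig"`.
#' @export
phantomConfig <- function(frames, size = c(64, 64),
                          closureSchedule = data.frame(start = integer(0),
                                                       end = integer(0)),
                          noiseSigma = 0.03, seed = 0,
                          anteriorAttachment = FALSE) {
  stopifnot(frames >= 1, length(size) == 2, all(size >= 32))
  ev <- closureSchedule
  .check_events(ev, "closureSchedule")
  if (nrow(ev) && (min(ev$start) < 0 || max(ev$end) > frames - 1))
    stop("scheduled events fall outside 0..frames-1")
  structure(list(frames = as.integer(frames), size = as.integer(size),
                 closureSchedule = ev, noiseSigma = noiseSigma,
                 seed = seed,
                 anteriorAttachment = isTRUE(anteriorAttachment)),
            class = "PhantomConfig")
}

# label ids of the speech set
.PH <- list(head = 1L, palate = 2L, jaw = 3L, tongue = 4L, tract = 5L,
            tooth = 6L)

.phantom_mask <- function(H, W, closed, anterior = FALSE) {
  g <- matrix(0L, H, W)
  rr <- function(f) max(1L, min(as.integer(round(f * H)), H))
  cc <- function(f) max(1L, min(as.integer(round(f * W)), W))
  # head: top band + posterior pharyngeal wall
  g[rr(0.06):rr(0.18), cc(0.06):cc(0.94)] <- .PH$head
  wall0 <- cc(0.80); wall1 <- cc(0.86)
  g[rr(0.18):rr(0.60), wall0:wall1] <- .PH$head
  # jaw, tooth space, tongue, vocal-tract airway
  g[rr(0.86):rr(0.96), cc(0.10):cc(0.60)] <- .PH$jaw
  g[rr(0.70):rr(0.78), cc(0.10):cc(0.16)] <- .PH$tooth
  cy <- 0.68 * H; cx <- 0.38 * W; ry <- 0.14 * H; rx <- 0.16 * W
  for (r in rr(0.54):rr(0.82)) for (cl in cc(0.22):cc(0.54))
    if (((r - cy) / ry)^2 + ((cl - cx) / rx)^2 <= 1) g[r, cl] <- .PH$tongue
  g[rr(0.42):rr(0.52), cc(0.18):cc(0.74)] <- .PH$tract
  # soft palate flap: tip touches the wall when closed, >= 2 px gap open
  p0 <- rr(0.30); p1 <- rr(0.36)
  pc0 <- cc(0.42)
  tip <- if (closed) wall0 - 1L else wall0 - 4L
  g[p0:p1, pc0:tip] <- .PH$palate
  if (anterior) g[(rr(0.18) + 1L):p1, pc0:(pc0 + 1L)] <- .PH$palate
  g
}

.phantom_levels <- c(background = 0.08, head = 0.85, soft_palate = 0.65,
                     jaw = 0.75, tongue = 0.55, vocal_tract = 0.12,
                     tooth_space = 0.25)

#' Generate a phantom series
#'
#' @param config a [phantomConfig()].
#' @return list with `images` (list of H x W matrices in [0, 1]), `masks`
#'   (list of [LabelMask-class]) and `closure` (the scheduled
#'   [ClosureSequence-class]). Every mask contains all 7 labels, and
#'   running [detectClosureFrame()] over the masks reproduces `closure`
#'   exactly (full-frame ROI; posterior ROI needed when
#'   `anteriorAttachment` is on).
#' @export
generatePhantomSequence <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  H <- config$size[1]; W <- config$size[2]
  closedVec <- eventsToSequence(config$closureSchedule, config$frames)
  .with_seed(config$seed, {
    masks <- vector("list", config$frames)
    images <- vector("list", config$frames)
    for (t in seq_len(config$frames)) {
      g <- .phantom_mask(H, W, closedVec[t] == 1L,
                         config$anteriorAttachment)
      masks[[t]] <- LabelMask(g, classNames = .speech_classes)
      base <- matrix(.phantom_levels[g + 1L], H, W)
      img <- base + matrix(rnorm(H * W, sd = config$noiseSigma), H, W)
      images[[t]] <- pmin(pmax(img, 0), 1)
    }
    list(images = images, masks = masks,
         closure = ClosureSequence(closedVec, "phantom"))
  })
}

#' Write a phantom series in the on-disk layout the pipeline consumes
#'
#' Creates `<dir>/frame_###.png`, `<dir>/mask_###.png` and
#' `<dir>/closure.csv`.
#'
#' @param series a [generatePhantomSequence()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantomSeries <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(series$images)) {
    writeImagePNG(series$images[[t]],
                  file.path(dir, sprintf("frame_%03d.png", t - 1L)))
    writeMaskPNG(series$masks[[t]],
                 file.path(dir, sprintf("mask_%03d.png", t - 1L)))
  }
  writeClosureCSV(series$closure, file.path(dir, "closure.csv"))
  invisible(dir)
}

#' Read a phantom series written by [writePhantomSeries()]
#' @param dir series directory.
#' @return list with `images`, `masks`, `closure` as in
#'   [generatePhantomSequence()].
#' @export
readPhantomSeries <- function(dir) {
  fr <- sort(list.files(dir, "^frame_", full.names = TRUE))
  mk <- sort(list.files(dir, "^mask_", full.names = TRUE))
  list(images = lapply(fr, readImagePNG),
       masks = lapply(mk, readMaskPNG),
       closure = readClosureCSV(file.path(dir, "closure.csv"),
                                basename(dir)))
}

#' Random multi-class blob masks
#'
#' Thresholded smoothed Gaussian noise, for exercising the
#' directional-field and metric oracles. Deterministic per seed; every
#' mask has at least one foreground pixel.
#'
#' @param n number of masks.
#' @param size c(H, W).
#' @param nClasses total classes including background (>= 2).
#' @param seed RNG seed.
#' @return list of [LabelMask-class] objects with labels in
#'   0..nClasses-1.
#' @export
generateBlobMasks <- function(n, size = c(32, 32), nClasses = 4, seed = 0) {
  H <- size[1]; W <- size[2]
  stopifnot(nClasses >= 2)
  k <- 5L
  g1 <- exp(-((seq_len(k) - (k + 1) / 2)^2) / 2)
  ker <- outer(g1, g1)
  ker <- array(ker / sum(ker), c(k, k, 1, 1))
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      z <- array(rnorm(H * W), c(H, W, 1, 1))
      for (rep in 1:2) z <- conv2d_fwd_cpp(z, ker, 0, (k - 1L) %/% 2L)
      zs <- matrix(z, H, W)
      q <- stats::quantile(zs, probs = seq_len(nClasses - 1) / nClasses)
      lab <- matrix(findInterval(zs, q), H, W)
      if (!any(lab > 0)) lab[H %/% 2, W %/% 2] <- 1L
      LabelMask(lab, classNames = c("background",
                                    paste0("class", seq_len(nClasses - 1))))
    })
  })
}
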