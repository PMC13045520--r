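## Model assembly: hybrid encoder + progressive refinement decoder.
##
## Architecture (speech configuration, 256x256 input):
##   stem: 3x (3x3 conv + BN + ReLU), 2x2 max-pool between layers -> /4
##   tokenize stem output into P x P patches (P = 16), project by E,
##   add E_pos, n transformer layers, reshape row-major to (H/4P, W/4P, D)
##   decoder: log2(4P) stages of [bilinear 2x up-sample, concat skip where
##   the resolution matches a stem stage, 3x3 conv + BN + ReLU]; the
##   shallowest nRefine stages carry a refinement module (1x1 DF head ->
##   2-channel field; N-step feature rectification; concat with F0 and 1x1
##   fusion); all refined maps are projected to numClasses channels,
##   up-sampled to the output resolution and summed with the decoder head.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Build a segmentation model
#'
#' Instantiates all weights for the encoder/decoder pair at a fixed input
#' size. Initialization: He-normal for convolutions, truncated normal
#' (sd 0.02) for transformer projections and position embeddings, BN
#' gamma = 1 / beta = 0; the DF heads start near zero so rectification
#' begins close to the identity warp.
#'
#' @param encoderConfig an [encoderConfig()].
#' @param decoderConfig a [decoderConfig()].
#' @param inputSize c(H, W); both must be divisible by 4 * patchSize.
#' @param seed integer seed for weight initialization.
#' @return A list of class `"dfsegModel"` with elements `params`, `state`
#'   (BN running statistics), `arch`, the two configs and `inputSize`.
#' @export
buildModel <- function(encoderConfig, decoderConfig,
                       inputSize = c(64, 64), seed = 0) {
  ec <- encoderConfig; dc <- decoderConfig
  H <- as.integer(inputSize[1]); W <- as.integer(inputSize[2])
  P <- ec$patchSize
  tot <- 4L * P
  if (H %% tot != 0 || W %% tot != 0)
    stop(sprintf(paste0("input %dx%d not divisible by stem downsampling x ",
                        "patch size = %d"), H, W, tot))
  hp <- H %/% tot; wp <- W %/% tot
  N <- hp * wp
  nStages <- as.integer(round(log2(tot)))
  widths <- dc$stageChannels
  if (is.null(widths)) {
    base3 <- c(256L, 128L, 64L)
    widths <- c(rep(256L, max(0L, nStages - 3L)),
                tail(base3, min(3L, nStages)))
  }
  if (length(widths) != nStages)
    stop(sprintf("stageChannels must have %d entries for patchSize %d",
                 nStages, P))
  if (dc$nRefine > nStages)
    stop("nRefine exceeds the number of decoder stages")
  # which stem stage (3 = deepest) feeds a skip into decoder stage i
  skipOf <- integer(nStages)
  for (i in seq_len(nStages)) {
    res <- hp * 2^i  # output rows of stage i
    skipOf[i] <- if (res == H %/% 4L) 3L else if (res == H %/% 2L) 2L
                 else if (res == H) 1L else 0L
  }
  refineStages <- if (dc$nRefine > 0)
    seq.int(nStages - dc$nRefine + 1L, nStages) else integer(0)

  sc <- ec$stemChannels; D <- ec$embedDim
  .with_seed(seed, {
    params <- list()
    state <- list()
    addCBR <- function(prefix, ci, co) {
      params[[paste0(prefix, ".W")]] <<- .he_conv(3L, ci, co)
      params[[paste0(prefix, ".b")]] <<- rep(0, co)
      params[[paste0(prefix, ".g")]] <<- rep(1, co)
      params[[paste0(prefix, ".be")]] <<- rep(0, co)
      state[[paste0(prefix, ".rm")]] <<- rep(0, co)
      state[[paste0(prefix, ".rv")]] <<- rep(1, co)
    }
    addCBR("stem1", 1L, sc[1])
    addCBR("stem2", sc[1], sc[2])
    addCBR("stem3", sc[2], sc[3])
    params$E <- matrix(.truncnorm(P * P * sc[3] * D), P * P * sc[3], D)
    params$Epos <- matrix(.truncnorm(N * D), N, D)
    for (l in seq_len(ec$depth))
      params <- c(params, .init_tf_layer(D, ec$mlpDim, paste0("tf", l)))
    cin <- D
    for (i in seq_len(nStages)) {
      csk <- if (skipOf[i] > 0) sc[skipOf[i]] else 0L
      addCBR(paste0("up", i), cin + csk, widths[i])
      cin <- widths[i]
    }
    for (i in refineStages) {
      wdt <- widths[i]
      params[[paste0("ref", i, ".dfW")]] <-
        array(.truncnorm(wdt * 2, sd = 0.01), c(1, 1, wdt, 2))
      params[[paste0("ref", i, ".dfb")]] <- rep(0, 2)
      params[[paste0("ref", i, ".fuseW")]] <- .he_conv(1L, 2L * wdt, wdt)
      params[[paste0("ref", i, ".fuseb")]] <- rep(0, wdt)
      # class projections start near zero so initial predictions are
      # close to uniform: a saturated softmax at init starves rare
      # classes of Dice gradient
      params[[paste0("agg", i, ".W")]] <-
        array(.truncnorm(wdt * dc$numClasses, sd = 0.01),
              c(1, 1, wdt, dc$numClasses))
      params[[paste0("agg", i, ".b")]] <- rep(0, dc$numClasses)
    }
    params$head.W <- array(.truncnorm(widths[nStages] * dc$numClasses,
                                      sd = 0.01),
                           c(1, 1, widths[nStages], dc$numClasses))
    params$head.b <- rep(0, dc$numClasses)
    structure(list(params = params, state = state,
                   encoderConfig = ec, decoderConfig = dc,
                   inputSize = c(H, W),
                   arch = list(hp = hp, wp = wp, N = N, nStages = nStages,
                               widths = widths, skipOf = skipOf,
                               refineStages = refineStages),
                   seed = seed),
              class = "dfsegModel")
  })
}

#' @export
print.dfsegModel <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("dfsegModel: input %dx%d, D=%d depth=%d P=%d, ",
                     "%d decoder stages, %d refinement modules (N=%d), ",
                     "%d classes, %s parameters\n"),
              x$inputSize[1], x$inputSize[2], x$encoderConfig$embedDim,
              x$encoderConfig$depth, x$encoderConfig$patchSize,
              x$arch$nStages, length(x$arch$refineStages),
              x$decoderConfig$rectSteps, x$decoderConfig$numClasses,
              format(np, big.mark = ",")))
  invisible(x)
}

# conv + BN + ReLU block
.cbr_fwd <- function(x, params, state, prefix, train) {
  cf <- conv_fwd(x, params[[paste0(prefix, ".W")]],
                 params[[paste0(prefix, ".b")]])
  bf <- bn_fwd(cf$y, params[[paste0(prefix, ".g")]],
               params[[paste0(prefix, ".be")]],
               state[[paste0(prefix, ".rm")]],
               state[[paste0(prefix, ".rv")]], train)
  rf <- relu_fwd(bf$y)
  list(y = rf$y,
       cache = list(conv = cf$cache, bn = bf$cache, relu = rf$cache),
       state = setNames(list(bf$rmean, bf$rvar),
                        paste0(prefix, c(".rm", ".rv"))))
}

.cbr_bwd <- function(dy, cache, prefix) {
  dr <- relu_bwd(dy, cache$relu)
  bb <- bn_bwd(dr, cache$bn)
  cb <- conv_bwd(bb$dx, cache$conv)
  g <- setNames(list(cb$dW, cb$db, bb$dgamma, bb$dbeta),
                paste0(prefix, c(".W", ".b", ".g", ".be")))
  list(dx = cb$dx, grads = g)
}

# full forward; x is [H,W,1,B]. Returns logits [H,W,C,B], dfs (list by
# stage), per-call BN state, and (optionally) every cache for backward.
model_forward_full <- function(model, x, train = FALSE, keepCache = TRUE) {
  p <- model$params; st <- model$state
  a <- model$arch; ec <- model$encoderConfig; dc <- model$decoderConfig
  newState <- list()
  cache <- if (keepCache) list() else NULL
  keep <- function(nm, val) if (keepCache) cache[[nm]] <<- val

  s1 <- .cbr_fwd(x, p, st, "stem1", train)
  newState <- c(newState, s1$state); keep("stem1", s1$cache)
  p1 <- pool_fwd(s1$y); keep("pool1", p1$cache)
  s2 <- .cbr_fwd(p1$y, p, st, "stem2", train)
  newState <- c(newState, s2$state); keep("stem2", s2$cache)
  p2 <- pool_fwd(s2$y); keep("pool2", p2$cache)
  s3 <- .cbr_fwd(p2$y, p, st, "stem3", train)
  newState <- c(newState, s3$state); keep("stem3", s3$cache)
  skips <- list(s1$y, s2$y, s3$y)

  pf <- patchify_fwd(s3$y, ec$patchSize); keep("patchify", pf$cache)
  em <- lin_fwd(pf$y, p$E, rep(0, ncol(p$E))); keep("embed", em$cache)
  B <- dim(x)[4]
  z <- em$y + array(p$Epos, c(a$N, ncol(p$E), B))
  for (l in seq_len(ec$depth)) {
    tf <- .tf_layer_fwd(z, p, paste0("tf", l), ec$heads)
    keep(paste0("tf", l), tf$cache)
    z <- tf$y
  }
  f <- tok2grid(z, a$hp, a$wp)

  dfs <- list(); refined <- list()
  for (i in seq_len(a$nStages)) {
    rs <- resize_fwd(f, dim(f)[1] * 2L, dim(f)[2] * 2L)
    keep(paste0("rs", i), rs$cache)
    xin <- if (a$skipOf[i] > 0) .cat_channels(rs$y, skips[[a$skipOf[i]]])
           else rs$y
    keep(paste0("upch", i), dim(rs$y)[3])
    ub <- .cbr_fwd(xin, p, st, paste0("up", i), train)
    newState <- c(newState, ub$state); keep(paste0("up", i), ub$cache)
    f <- ub$y
    if (i %in% a$refineStages) {
      dfc <- conv_fwd(f, p[[paste0("ref", i, ".dfW")]],
                      p[[paste0("ref", i, ".dfb")]])
      keep(paste0("dfhead", i), dfc$cache)
      dfi <- dfc$y
      Fk <- f; wcs <- vector("list", dc$rectSteps)
      for (k in seq_len(dc$rectSteps)) {
        wf <- warp_fwd(Fk, dfi)
        wcs[[k]] <- wf$cache
        Fk <- wf$y
      }
      keep(paste0("warps", i), wcs)
      cat2 <- .cat_channels(Fk, f)
      fu <- conv_fwd(cat2, p[[paste0("ref", i, ".fuseW")]],
                     p[[paste0("ref", i, ".fuseb")]])
      keep(paste0("fuse", i), fu$cache)
      dfs[[as.character(i)]] <- dfi
      refined[[as.character(i)]] <- fu$y
      f <- fu$y
    }
  }

  hd <- conv_fwd(f, p$head.W, p$head.b)
  keep("head", hd$cache)
  logits <- hd$y
  H <- dim(f)[1]; W <- dim(f)[2]
  for (i in a$refineStages) {
    key <- as.character(i)
    pr <- conv_fwd(refined[[key]], p[[paste0("agg", i, ".W")]],
                   p[[paste0("agg", i, ".b")]])
    keep(paste0("agg", i), pr$cache)
    y <- pr$y
    if (!all(dim(y)[1:2] == c(H, W))) {
      keep(paste0("aggdim", i), dim(y)[1:2])
      y <- resize_bilinear_fwd_cpp(y, H, W)
    }
    logits <- logits + y
  }
  list(logits = logits, dfs = dfs, newState = newState, cache = cache)
}

# backward; dlogits [H,W,C,B], dfsGrad named list (by stage) or NULL
model_backward_full <- function(model, fw, dlogits, dfsGrad = NULL) {
  p <- model$params; a <- model$arch; dc <- model$decoderConfig
  ec <- model$encoderConfig
  cache <- fw$cache
  grads <- list()
  addg <- function(g) for (nm in names(g))
    grads[[nm]] <<- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]

  hb <- conv_bwd(dlogits, cache$head)
  addg(setNames(list(hb$dW, hb$db), c("head.W", "head.b")))
  dcur <- hb$dx
  dRefined <- list()
  for (i in a$refineStages) {
    dy <- dlogits
    dd <- cache[[paste0("aggdim", i)]]
    if (!is.null(dd)) dy <- resize_bilinear_bwd_cpp(dy, dd[1], dd[2])
    ab <- conv_bwd(dy, cache[[paste0("agg", i)]])
    addg(setNames(list(ab$dW, ab$db),
                  paste0("agg", i, c(".W", ".b"))))
    dRefined[[as.character(i)]] <- ab$dx
  }

  dSkip <- list(NULL, NULL, NULL)
  for (i in rev(seq_len(a$nStages))) {
    if (i %in% a$refineStages) {
      key <- as.character(i)
      dfused <- dcur + dRefined[[key]]
      fb <- conv_bwd(dfused, cache[[paste0("fuse", i)]])
      addg(setNames(list(fb$dW, fb$db),
                    paste0("ref", i, c(".fuseW", ".fuseb"))))
      wdt <- a$widths[i]
      dFk <- fb$dx[, , seq_len(wdt), , drop = FALSE]
      dF0 <- fb$dx[, , wdt + seq_len(wdt), , drop = FALSE]
      ddf <- if (!is.null(dfsGrad[[key]])) dfsGrad[[key]] else 0
      wcs <- cache[[paste0("warps", i)]]
      for (k in rev(seq_len(dc$rectSteps))) {
        wb <- warp_bwd(dFk, wcs[[k]])
        dFk <- wb$dx
        ddf <- ddf + wb$ddf
      }
      dF0 <- dF0 + dFk
      if (!identical(ddf, 0)) {
        db <- conv_bwd(ddf, cache[[paste0("dfhead", i)]])
        addg(setNames(list(db$dW, db$db),
                      paste0("ref", i, c(".dfW", ".dfb"))))
        dF0 <- dF0 + db$dx
      }
      dcur <- dF0
    }
    ub <- .cbr_bwd(dcur, cache[[paste0("up", i)]], paste0("up", i))
    addg(ub$grads)
    upch <- cache[[paste0("upch", i)]]
    dxin <- ub$dx
    if (a$skipOf[i] > 0) {
      sidx <- a$skipOf[i]
      dsk <- dxin[, , -seq_len(upch), , drop = FALSE]
      dSkip[[sidx]] <- if (is.null(dSkip[[sidx]])) dsk
                       else dSkip[[sidx]] + dsk
      dxin <- dxin[, , seq_len(upch), , drop = FALSE]
    }
    dcur <- resize_bwd(dxin, cache[[paste0("rs", i)]])
  }

  dz <- grid2tok(dcur)
  for (l in rev(seq_len(ec$depth))) {
    tb <- .tf_layer_bwd(dz, cache[[paste0("tf", l)]], p,
                        paste0("tf", l), ec$heads)
    addg(tb$grads)
    dz <- tb$dx
  }
  addg(list(Epos = apply(dz, c(1, 2), sum)))
  eb <- lin_bwd(dz, cache$embed)
  addg(list(E = eb$dW))  # the projection E carries no bias term
  dS3 <- patchify_bwd(eb$dx, cache$patchify)

  if (!is.null(dSkip[[3]])) dS3 <- dS3 + dSkip[[3]]
  b3 <- .cbr_bwd(dS3, cache$stem3, "stem3")
  addg(b3$grads)
  dS2 <- pool_bwd(b3$dx, cache$pool2)
  if (!is.null(dSkip[[2]])) dS2 <- dS2 + dSkip[[2]]
  b2 <- .cbr_bwd(dS2, cache$stem2, "stem2")
  addg(b2$grads)
  dS1 <- pool_bwd(b2$dx, cache$pool1)
  if (!is.null(dSkip[[1]])) dS1 <- dS1 + dSkip[[1]]
  b1 <- .cbr_bwd(dS1, cache$stem1, "stem1")
  addg(b1$grads)
  grads
}

#' Forward pass: image(s) to class logits and predicted directional fields
#'
#' @param model a [buildModel()] result.
#' @param images a single H x W numeric matrix or a list of them, already
#'   intensity-normalized to roughly [0, 1] (see [normalizeFrame()]).
#' @param train logical; TRUE uses batch statistics in the BN layers and
#'   updates the model's running statistics (the updated model is attached
#'   as attribute `"model"` of the result for the trainer's use).
#' @return list with `logits` (H x W x numClasses for a single image,
#'   H x W x C x B for a list) and `dfs`, the per-refinement-module
#'   predicted fields (deepest first).
#' @export
modelForward <- function(model, images, train = FALSE) {
  single <- !is.list(images)
  if (single) images <- list(images)
  H <- model$inputSize[1]; W <- model$inputSize[2]
  B <- length(images)
  x <- array(0, c(H, W, 1L, B))
  for (b in seq_len(B)) {
    im <- images[[b]]
    if (!all(dim(im) == c(H, W)))
      stop(sprintf("frame %d is %dx%d; model was built for %dx%d",
                   b, nrow(im), ncol(im), H, W))
    x[, , 1L, b] <- im
  }
  fw <- model_forward_full(model, x, train = train, keepCache = FALSE)
  logits <- fw$logits
  dfs <- fw$dfs
  if (single) {
    logits <- array(logits, dim(logits)[1:3])
    dfs <- lapply(dfs, function(d) array(d, dim(d)[1:3]))
  }
  out <- list(logits = logits, dfs = dfs)
  if (train) {
    model$state[names(fw$newState)] <- fw$newState
    attr(out, "model") <- model
  }
  out
}

#' Per-pixel class probabilities from logits
#' @param logits H x W x C array.
#' @return H x W x C array of softmax probabilities (channels sum to 1).
#' @export
softmaxProbs <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:2]), d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

#' Convert logits to a LabelMask by per-pixel argmax
#' @param logits H x W x C array.
#' @param classNames optional class names for the result.
#' @return A [LabelMask-class] with labels 0..C-1.
#' @export
logitsToMask <- function(logits, classNames = NULL) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:2]), d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  LabelMask(matrix(as.integer(lab), d[1], d[2]), classNames = classNames)
}

#' Min-max normalize one image frame to [0, 1]
#' @param image numeric matrix.
#' @return matrix scaled so min = 0, max = 1 (constant frames become 0).
#' @export
normalizeFrame <- function(image) {
  r <- suppressWarnings(range(image, finite = TRUE))
  if (is.finite(r[1]) && r[2] > r[1]) (image - r[1]) / (r[2] - r[1])
  else image * 0
}
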