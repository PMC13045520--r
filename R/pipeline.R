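## Training / evaluation / cross-validation orchestration.
##
## Training optimizes Dice loss plus lambda times the sum of the
## directional-field supervision losses over the refinement modules, with
## Adam at the configured hyperparameters. The GT directional field of
## every training mask is computed once at full resolution (per-class
## mode) and decimated by nearest-index to each refinement module's
## resolution. "Validation accuracy" for best-model selection is the mean
## foreground Dice on the validation frames.

#' Training configuration
#'
#' Defaults follow the speech MRI experiments: Adam with beta1 = 0.9,
#' beta2 = 0.999, eps = 1e-8, learning rate 2e-4, batch size 8, 150
#' epochs.
#'
#' @param lr learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param betas Adam (beta1, beta2).
#' @param eps Adam epsilon.
#' @param dfLossWeight lambda multiplying the summed DF losses (0 turns
#'   DF supervision off).
#' @param seed seed controlling weight init and batch shuffling.
#' @return list of class `"TrainConfig"`.
#' @export
trainConfig <- function(lr = 2e-4, batchSize = 8, epochs = 150,
                        betas = c(0.9, 0.999), eps = 1e-8,
                        dfLossWeight = 1.0, seed = 0) {
  stopifnot(lr > 0, batchSize >= 1, epochs >= 1, all(betas > 0),
            all(betas < 1), eps > 0, dfLossWeight >= 0)
  structure(list(lr = lr, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), betas = betas, eps = eps,
                 dfLossWeight = dfLossWeight, seed = seed),
            class = "TrainConfig")
}

#' Subject-wise 5-fold cross-validation assignment
#'
#' Rotation rule: fold k tests series k, validates on the next series
#' (cyclically) and trains on the remaining three, so every series is the
#' test set exactly once.
#'
#' @param seriesIds exactly 5 series identifiers (use `k` for a
#'   generalized k-fold).
#' @param k number of folds; defaults to `length(seriesIds)` but the
#'   canonical configuration is 5.
#' @return list of class `"FoldSpec"`: one element per fold with `train`,
#'   `val`, `test` id vectors.
#' @export
makeFolds <- function(seriesIds, k = 5) {
  if (length(seriesIds) != k)
    stop(sprintf("expected %d series ids, got %d", k, length(seriesIds)))
  if (anyDuplicated(seriesIds)) stop("series ids must be unique")
  folds <- lapply(seq_len(k), function(i) {
    test <- seriesIds[i]
    val <- seriesIds[if (i == k) 1L else i + 1L]
    list(train = setdiff(seriesIds, c(test, val)), val = val, test = test)
  })
  structure(folds, class = "FoldSpec")
}

#' @export
print.FoldSpec <- function(x, ...) {
  for (i in seq_along(x))
    cat(sprintf("fold %d: test=%s val=%s train=%s\n", i, x[[i]]$test,
                x[[i]]$val, paste(x[[i]]$train, collapse = ",")))
  invisible(x)
}

# precompute per-refinement-stage DF targets for a set of masks
.df_targets <- function(masks, model) {
  a <- model$arch
  H <- model$inputSize[1]
  lapply(masks, function(m) {
    full <- dfVectors(computeDF(m))
    fgFull <- maskGrid(m) > 0L
    out <- list()
    for (i in a$refineStages) {
      s <- 2^(a$nStages - i)
      out[[as.character(i)]] <- list(
        df = decimateDF(full, s),
        fg = fgFull[seq(1, nrow(fgFull), by = s),
                    seq(1, ncol(fgFull), by = s), drop = FALSE])
    }
    out
  })
}

#' Train a segmentation model
#'
#' @param model a [buildModel()] result (or NULL to build one from the
#'   configs at the size of the first image).
#' @param images list of H x W frames (raw; min-max normalized here).
#' @param masks list of matching [LabelMask-class] ground truth.
#' @param config a [trainConfig()].
#' @param valImages,valMasks optional validation split; when given, the
#'   parameters with the best validation mean foreground Dice are kept.
#' @param maxSteps optional cap on total optimizer steps (overrides
#'   epochs when smaller); used by smoke tests.
#' @param encoderConfig,decoderConfig used only when `model` is NULL.
#' @param verbose print per-epoch progress.
#' @return list of class `"dfsegFit"`: `model` (final), `bestModel`
#'   (best-validation, or final when no validation set), `history`
#'   (data.frame of step losses) and `valHistory`.
#' @export
trainModel <- function(model, images, masks, config = trainConfig(),
                       valImages = NULL, valMasks = NULL, maxSteps = Inf,
                       encoderConfig = tinyEncoderConfig(),
                       decoderConfig = tinyDecoderConfig(),
                       verbose = FALSE) {
  stopifnot(length(images) == length(masks))
  if (is.null(model))
    model <- buildModel(encoderConfig, decoderConfig,
                        inputSize = dim(images[[1]]), seed = config$seed)
  n <- length(images)
  H <- model$inputSize[1]; W <- model$inputSize[2]
  xs <- lapply(images, normalizeFrame)
  dfT <- if (model$decoderConfig$nRefine > 0 && config$dfLossWeight > 0)
    .df_targets(masks, model) else NULL
  opt <- adam_init(model$params)
  hist <- list()
  best <- list(dice = -Inf, params = NULL, state = NULL)
  valHist <- list()
  step <- 0L
  .with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      bstarts <- seq(1, n, by = config$batchSize)
      for (bs in bstarts) {
        if (step >= maxSteps) break
        idx <- ord[bs:min(bs + config$batchSize - 1L, n)]
        B <- length(idx)
        x <- array(0, c(H, W, 1L, B))
        for (j in seq_len(B)) x[, , 1L, j] <- xs[[idx[j]]]
        fw <- model_forward_full(model, x, train = TRUE, keepCache = TRUE)
        model$state[names(fw$newState)] <- fw$newState
        dl <- .dice_loss_grad(fw$logits, masks[idx])
        dfsGrad <- NULL
        dfLossTotal <- 0
        if (!is.null(dfT)) {
          dfsGrad <- list()
          for (key in names(fw$dfs)) {
            pd <- fw$dfs[[key]]
            d <- dim(pd)
            gt <- array(0, d)
            fg <- array(FALSE, c(d[1], d[2], B))
            for (j in seq_len(B)) {
              tj <- dfT[[idx[j]]][[key]]
              gt[, , , j] <- tj$df
              fg[, , j] <- tj$fg
            }
            dg <- .df_loss_grad(pd, gt, fg)
            dfLossTotal <- dfLossTotal + dg$loss
            dfsGrad[[key]] <- config$dfLossWeight * dg$dpred
          }
        }
        loss <- dl$loss + config$dfLossWeight * dfLossTotal
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at step %d (dice %.4f, df %.4f)",
                       step + 1L, dl$loss, dfLossTotal))
        grads <- model_backward_full(model, fw, dl$dlogits, dfsGrad)
        up <- adam_step(model$params, grads, opt, config$lr,
                        config$betas[1], config$betas[2], config$eps)
        model$params <- up$params
        opt <- up$st
        step <- step + 1L
        hist[[step]] <- data.frame(step = step, epoch = ep,
                                   loss = loss, dice_loss = dl$loss,
                                   df_loss = dfLossTotal)
        if (verbose && step %% 10 == 0)
          message(sprintf("step %d: loss %.4f (dice %.4f, df %.4f)",
                          step, loss, dl$loss, dfLossTotal))
      }
      if (!is.null(valImages)) {
        vd <- .mean_fg_dice(model, valImages, valMasks)
        valHist[[length(valHist) + 1L]] <-
          data.frame(epoch = ep, val_dice = vd)
        if (vd > best$dice)
          best <- list(dice = vd, params = model$params,
                       state = model$state)
      }
      if (step >= maxSteps) break
    }
  })
  bestModel <- model
  if (!is.null(best$params)) {
    bestModel$params <- best$params
    bestModel$state <- best$state
  }
  structure(list(model = model, bestModel = bestModel,
                 history = do.call(rbind, hist),
                 valHistory = if (length(valHist))
                   do.call(rbind, valHist) else NULL,
                 config = config),
            class = "dfsegFit")
}

.mean_fg_dice <- function(model, images, masks) {
  preds <- predictMasks(model, images)
  C <- model$decoderConfig$numClasses
  mean(vapply(seq_along(preds), function(i)
    mean(vapply(seq_len(C - 1L), function(lab)
      diceCoefficient(preds[[i]], masks[[i]], lab), numeric(1))),
    numeric(1)))
}

#' Predict label masks for a list of frames
#'
#' Frames are min-max normalized, passed through the model in evaluation
#' mode (BN running statistics) and converted to masks by per-pixel
#' argmax.
#'
#' @param model a trained model (or `fit$bestModel`).
#' @param images list of H x W frames.
#' @param batchSize frames per forward pass.
#' @return list of [LabelMask-class] predictions.
#' @export
predictMasks <- function(model, images, batchSize = 8L) {
  cn <- if (model$decoderConfig$numClasses == 7L) .speech_classes else NULL
  out <- vector("list", length(images))
  for (bs in seq(1, length(images), by = batchSize)) {
    idx <- bs:min(bs + batchSize - 1L, length(images))
    fw <- modelForward(model, lapply(images[idx], normalizeFrame))
    lg <- fw$logits
    if (length(idx) == 1L) {
      out[[idx]] <- logitsToMask(array(lg, dim(lg)[1:3]), cn)
    } else {
      for (j in seq_along(idx))
        out[[idx[j]]] <- logitsToMask(array(lg[, , , j], dim(lg)[1:3]), cn)
    }
  }
  out
}

#' Evaluate a model (or precomputed predictions) against ground truth
#'
#' @param model a model, or NULL when `pred` is given.
#' @param images frames to segment (ignored when `pred` given).
#' @param gtMasks ground-truth [LabelMask-class] list.
#' @param pred optional list of predicted masks.
#' @param spacing optional numeric(2) pixel spacing (mm).
#' @return an evaluation report from [evaluateMasks()].
#' @export
evaluateModel <- function(model, images, gtMasks, pred = NULL,
                          spacing = NULL) {
  if (is.null(pred)) {
    if (model$decoderConfig$numClasses !=
        length(classNames(gtMasks[[1]])))
      stop("model and ground truth disagree on the class count")
    pred <- predictMasks(model, images)
  }
  evaluateMasks(pred, gtMasks, spacing = spacing)
}

#' Frame- and event-level closure report for one series
#'
#' Runs [detectClosureFrame()] over the predicted masks, extracts events
#' and, when GT closure labels are available, computes frame accuracy and
#' the event-match counts.
#'
#' @param predMasks list of predicted [LabelMask-class] frames.
#' @param gtClosure optional [ClosureSequence-class] ground truth.
#' @param roi optional closure ROI (see [detectClosureFrame()]).
#' @param outDir optional directory for the CSV reports
#'   (`closure_frames.csv`, `closure_events.csv`).
#' @return list with `predSequence`, `predEvents`, and (with GT) `frames`
#'   (accuracy percentages) and `events` (an `"EventMatchReport"`).
#' @export
closureReport <- function(predMasks, gtClosure = NULL, roi = NULL,
                          outDir = NULL) {
  predSeq <- detectClosureSequence(predMasks, roi = roi)
  predEv <- extractEvents(predSeq)
  out <- list(predSequence = predSeq, predEvents = predEv)
  if (!is.null(gtClosure)) {
    out$frames <- frameAccuracy(gtClosure, predSeq)
    out$events <- matchEvents(extractEvents(gtClosure), predEv)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$frames))
      write.csv(data.frame(t(out$frames)),
                file.path(outDir, "closure_frames.csv"),
                row.names = FALSE)
    ev <- if (!is.null(out$events)) out$events
          else matchEvents(predEv, predEv)
    writeEventReport(ev, csv = file.path(outDir, "closure_events.csv"))
  }
  out
}

#' Ablation sweep over the refinement-module count
#'
#' Trains one model per `nRefine` value on the given frames and reports
#' the mean foreground Dice of each arm on its evaluation frames,
#' producing a table shaped like a refinement-count ablation.
#'
#' @param images,masks training frames and GT.
#' @param nRefineValues refinement counts to sweep (default 0:4).
#' @param config a [trainConfig()].
#' @param maxSteps step cap per arm.
#' @param evalImages,evalMasks evaluation split (defaults to the training
#'   frames).
#' @param encoderConfig encoder config for every arm.
#' @param stageChannels decoder stage widths for every arm.
#' @param csv optional output CSV path.
#' @return data.frame with columns `n_refine`, `mean_dice`.
#' @export
runAblation <- function(images, masks, nRefineValues = 0:4,
                        config = trainConfig(), maxSteps = 60,
                        evalImages = images, evalMasks = masks,
                        encoderConfig = tinyEncoderConfig(),
                        stageChannels = tinyDecoderConfig()$stageChannels,
                        csv = NULL) {
  rows <- lapply(nRefineValues, function(nr) {
    dc <- decoderConfig(stageChannels = stageChannels, nRefine = nr,
                        rectSteps = 6,
                        numClasses = length(classNames(masks[[1]])))
    fit <- trainModel(NULL, images, masks, config, maxSteps = maxSteps,
                      encoderConfig = encoderConfig, decoderConfig = dc)
    data.frame(n_refine = nr,
               mean_dice = .mean_fg_dice(fit$model, evalImages, evalMasks))
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' Save a model checkpoint
#'
#' Single-file archive of weights, BN state, configs, seed and history;
#' round-trips through [loadCheckpoint()].
#'
#' @param fit a `"dfsegFit"` or bare `"dfsegModel"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(fit, path) {
  obj <- if (inherits(fit, "dfsegFit"))
    list(model = fit$bestModel, history = fit$history,
         config = fit$config, version = "1")
  else list(model = fit, history = NULL, config = NULL, version = "1")
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file from [saveCheckpoint()].
#' @return list with `model`, `history`, `config`.
#' @export
loadCheckpoint <- function(path) readRDS(path)
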