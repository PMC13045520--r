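# Shared fixtures, all generated in code.

# micro model: 16x16 input, 3 decoder stages, 2 refinement modules
micro_model <- function(seed = 1, nRefine = 2, rectSteps = 3,
                        numClasses = 4) {
  ec <- encoderConfig(stemChannels = c(4, 6, 8), patchSize = 2,
                      embedDim = 16, depth = 1, heads = 2, mlpDim = 24)
  dc <- decoderConfig(stageChannels = c(12, 10, 8), nRefine = nRefine,
                      rectSteps = rectSteps, numClasses = numClasses)
  buildModel(ec, dc, inputSize = c(16, 16), seed = seed)
}

# small training phantom series (32x32 keeps per-step cost low)
small_phantom <- function(frames = 6, seed = 7, size = c(32, 32),
                          schedule = if (frames >= 4)
                            data.frame(start = 2, end = 3)
                          else data.frame(start = integer(0),
                                          end = integer(0))) {
  generatePhantomSequence(phantomConfig(frames = frames, size = size,
                                        closureSchedule = schedule,
                                        noiseSigma = 0.03, seed = seed))
}

# independent R-side Hausdorff oracle: exhaustive pairwise distances over
# boundary sets extracted by the pure-R boundary scan
hausdorff_oracle <- function(pred, gt, label) {
  bin_coords <- function(m) {
    g <- matrix(as.integer(maskGrid(m) == label), nrow(maskGrid(m)))
    dfseg:::boundary_list_r(g, 1L, 8L)
  }
  A <- bin_coords(pred); B <- bin_coords(gt)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  D <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}
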