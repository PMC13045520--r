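# Progressive refinement decoder: DF head, feature rectification, fusion,
# aggregation and the full forward contract.

test_that("decoder config enforces refinement invariants", {
  expect_error(decoderConfig(nRefine = 5), "nRefine")
  expect_error(decoderConfig(nRefine = 1, rectSteps = 0), "rectSteps")
  expect_equal(speechDecoderConfig()$rectSteps, 6)
  expect_equal(speechDecoderConfig()$numClasses, 7)
  # more refinement modules than decoder stages is rejected at build
  ec <- encoderConfig(stemChannels = c(4, 6, 8), patchSize = 2,
                      embedDim = 16, depth = 0, heads = 2, mlpDim = 24)
  expect_error(buildModel(ec, decoderConfig(stageChannels = c(8, 8, 8),
                                            nRefine = 4, numClasses = 4),
                          inputSize = c(16, 16)), "exceeds")
})

test_that("dfHead is a pointwise map to exactly 2 channels", {
  set.seed(1)
  f <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  W <- matrix(rnorm(6), 3, 2)
  out <- dfHead(f, W, c(0.5, -0.5))
  expect_equal(dim(out), c(6, 5, 2))
  # pointwise: each output pixel is the channel vector times W plus bias
  expect_equal(as.numeric(out[2, 3, ]),
               as.numeric(f[2, 3, ] %*% W) + c(0.5, -0.5))
  # zero weights give a zero field, so rectification is the identity
  z <- dfHead(f, matrix(0, 3, 2))
  expect_true(all(z == 0))
  expect_equal(frfRectify(f, z, steps = 4), f)
})

test_that("rectification with a zero field is the exact identity for any N", {
  set.seed(2)
  f <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  z <- array(0, c(8, 8, 2))
  for (N in c(0, 1, 3, 6))
    expect_identical(frfRectify(f, z, N), f)
})

test_that("constant unit fields shift a ramp with border clamping", {
  H <- 5; W <- 7
  ramp <- array(rep(0:(W - 1), each = H), c(H, W, 1))
  one_x <- array(rep(c(1, 0), each = H * W), c(H, W, 2))
  # N = 1: value x+1 everywhere except the last column, which clamps
  r1 <- frfRectify(ramp, one_x, 1)
  expect_equal(r1[, 1:(W - 1), 1],
               matrix(rep(1:(W - 1), each = H), H), tolerance = 0)
  expect_equal(r1[, W, 1], rep(W - 1, H))
  # N = 3: three-column shift with a clamped band of width 3
  r3 <- frfRectify(ramp, one_x, 3)
  expect_equal(r3[, , 1],
               matrix(rep(pmin(0:(W - 1) + 3, W - 1), each = H), H),
               tolerance = 0)
  # same law along rows for the dy channel
  rampr <- array(rep(0:(H - 1), W), c(H, W, 1))
  one_y <- array(rep(c(0, 1), each = H * W), c(H, W, 2))
  r1y <- frfRectify(rampr, one_y, 1)
  expect_equal(r1y[, 1, 1], pmin(0:(H - 1) + 1, H - 1))
  expect_error(frfRectify(ramp, one_x, -1), ">= 0")
})

test_that("fractional displacements interpolate bilinearly", {
  f <- array(c(0, 0, 1, 1), c(2, 2, 1))  # columns 0 and 1
  half <- array(rep(c(0.5, 0), each = 4), c(2, 2, 2))
  r <- frfRectify(f, half, 1)
  expect_equal(r[, 1, 1], c(0.5, 0.5))  # halfway between the columns
  expect_equal(r[, 2, 1], c(1, 1))      # clamped at the right border
})

test_that("aggregation adds up-sampled class projections onto the head output", {
  set.seed(3)
  dec <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  headp <- list(W = array(rnorm(3 * 4), c(1, 1, 3, 4)), b = rep(0, 4))
  # no refined maps: logits are the head projection alone
  base <- aggregateLogits(list(), dec, list(headp))
  expect_equal(dim(base), c(8, 8, 4))
  # an all-zero refined map (zero bias projection) changes nothing
  zmap <- array(0, c(4, 4, 2))
  proj <- list(W = array(rnorm(2 * 4), c(1, 1, 2, 4)), b = rep(0, 4))
  same <- aggregateLogits(list(zmap), dec, list(proj, headp))
  expect_equal(same, base)
  # a non-zero low-resolution map is up-sampled before the sum
  rmap <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  out <- aggregateLogits(list(rmap), dec, list(proj, headp))
  expect_equal(dim(out), c(8, 8, 4))
  expect_false(isTRUE(all.equal(out, base)))
})

test_that("model forward meets the shape, softmax and determinism contract", {
  ec <- tinyEncoderConfig()
  dc <- tinyDecoderConfig()
  m <- buildModel(ec, dc, inputSize = c(64, 64), seed = 0)
  x <- matrix(runif(64 * 64), 64, 64)
  fw <- modelForward(m, x)
  expect_equal(dim(fw$logits), c(64, 64, 7))
  expect_equal(length(fw$dfs), 3)
  for (d in fw$dfs) expect_equal(dim(d)[3], 2)
  pr <- softmaxProbs(fw$logits)
  expect_equal(apply(pr, c(1, 2), sum), matrix(1, 64, 64),
               tolerance = 1e-12)
  expect_identical(modelForward(m, x)$logits, fw$logits)
})

test_that("with three modules the refinements follow the three skip stages", {
  m <- buildModel(tinyEncoderConfig(), tinyDecoderConfig(),
                  inputSize = c(64, 64), seed = 0)
  # stages 2..4 carry the stem skips (deepest first); nRefine = 3 modules
  # sit exactly there
  expect_equal(which(m$arch$skipOf > 0), 2:4)
  expect_equal(m$arch$refineStages, 2:4)
  # a single module sits at the final (full-resolution) layer
  m1 <- buildModel(tinyEncoderConfig(),
                   decoderConfig(stageChannels = tinyDecoderConfig()$stageChannels,
                                 nRefine = 1),
                   inputSize = c(64, 64), seed = 0)
  expect_equal(m1$arch$refineStages, 4L)
})

test_that("nRefine = 0 collapses to a plain skip decoder that still runs", {
  dc0 <- decoderConfig(stageChannels = tinyDecoderConfig()$stageChannels,
                       nRefine = 0, numClasses = 7)
  m <- buildModel(tinyEncoderConfig(), dc0, inputSize = c(64, 64), seed = 0)
  fw <- modelForward(m, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(fw$logits), c(64, 64, 7))
  expect_equal(length(fw$dfs), 0)
})

test_that("analytic gradients match finite differences through the whole net", {
  m <- micro_model(seed = 1)
  set.seed(3)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  masks <- lapply(1:2, function(i)
    LabelMask(matrix(sample(0:3, 256, TRUE), 16, 16),
              classNames = c("bg", "a", "b", "c")))
  dfT <- dfseg:::.df_targets(masks, m)
  lossfun <- function(model) {
    fw <- dfseg:::model_forward_full(model, x, train = TRUE,
                                     keepCache = FALSE)
    tot <- dfseg:::.dice_loss_grad(fw$logits, masks)$loss
    for (key in names(fw$dfs)) {
      d <- dim(fw$dfs[[key]])
      gt <- array(0, d); fg <- array(FALSE, c(d[1], d[2], 2))
      for (j in 1:2) {
        tj <- dfT[[j]][[key]]
        gt[, , , j] <- tj$df; fg[, , j] <- tj$fg
      }
      tot <- tot + dfseg:::.df_loss_grad(fw$dfs[[key]], gt, fg)$loss
    }
    tot
  }
  fw <- dfseg:::model_forward_full(m, x, train = TRUE, keepCache = TRUE)
  dl <- dfseg:::.dice_loss_grad(fw$logits, masks)
  dfsGrad <- list()
  for (key in names(fw$dfs)) {
    d <- dim(fw$dfs[[key]])
    gt <- array(0, d); fg <- array(FALSE, c(d[1], d[2], 2))
    for (j in 1:2) {
      tj <- dfT[[j]][[key]]
      gt[, , , j] <- tj$df; fg[, , j] <- tj$fg
    }
    dfsGrad[[key]] <- dfseg:::.df_loss_grad(fw$dfs[[key]], gt, fg)$dpred
  }
  gr <- dfseg:::model_backward_full(m, fw, dl$dlogits, dfsGrad)
  expect_setequal(names(gr), names(m$params))
  set.seed(9)
  probe <- c("ref2.dfW", "ref3.fuseW", "up2.W", "stem2.W", "tf1.Wv",
             "E", "Epos", "head.W", "agg3.W")
  for (nm in probe) {
    i <- sample(length(m$params[[nm]]), 1)
    eps <- 1e-5
    m2 <- m
    m2$params[[nm]][i] <- m$params[[nm]][i] + eps
    lp <- lossfun(m2)
    m2$params[[nm]][i] <- m$params[[nm]][i] - eps
    lm <- lossfun(m2)
    fd <- (lp - lm) / (2 * eps)
    an <- gr[[nm]][i]
    expect_lt(abs(fd - an) / max(1e-4, abs(fd), abs(an)), 1e-3,
              label = paste("gradient of", nm))
  }
})

test_that("DF heads get gradient from DF supervision and decoder weights from Dice", {
  m <- micro_model(seed = 2)
  set.seed(4)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  masks <- list(LabelMask(matrix(sample(0:3, 256, TRUE), 16, 16),
                          classNames = c("bg", "a", "b", "c")))
  fw <- dfseg:::model_forward_full(m, x, train = TRUE, keepCache = TRUE)
  dl <- dfseg:::.dice_loss_grad(fw$logits, masks)
  # dice-only backward reaches every decoder stage
  gr <- dfseg:::model_backward_full(m, fw, dl$dlogits, NULL)
  for (nm in c("up1.W", "up2.W", "up3.W", "head.W"))
    expect_gt(max(abs(gr[[nm]])), 0, label = nm)
  # df-only backward reaches both DF heads
  dfT <- dfseg:::.df_targets(masks, m)
  dfsGrad <- list()
  for (key in names(fw$dfs)) {
    d <- dim(fw$dfs[[key]])
    gt <- array(0, d); fg <- array(FALSE, c(d[1], d[2], 1))
    tj <- dfT[[1]][[key]]
    gt[, , , 1] <- tj$df; fg[, , 1] <- tj$fg
    dfsGrad[[key]] <- dfseg:::.df_loss_grad(fw$dfs[[key]], gt, fg)$dpred
  }
  gr2 <- dfseg:::model_backward_full(m, fw, dl$dlogits * 0, dfsGrad)
  for (nm in c("ref2.dfW", "ref2.dfb", "ref3.dfW", "ref3.dfb"))
    expect_gt(max(abs(gr2[[nm]])), 0, label = nm)
})
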