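# Dice loss, DF supervision loss, Dice coefficient, Hausdorff distance.

test_that("dice loss is ~0 on exact predictions and ~1 on the complement", {
  g <- matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4)
  m <- LabelMask(g, classNames = c("bg", "fg"))
  oh <- array(0, c(4, 4, 2))
  oh[, , 1] <- g == 0L
  oh[, , 2] <- g == 1L
  expect_lt(diceLoss(oh, m), 1e-4)
  expect_gt(diceLoss(oh[, , 2:1], m), 0.999)
  expect_error(diceLoss(array(0.5, c(3, 3, 2)), m), "mismatch")
})

test_that("dice loss on uniform probabilities matches the closed form", {
  # 4x4 mask, half foreground, uniform p = 1/2 per class:
  # dice = (2*0.5*8 + eps) / (0.5*16 + 8 + eps) = 0.5 -> loss 0.5
  g <- matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4)
  m <- LabelMask(g, classNames = c("bg", "fg"))
  u <- array(0.5, c(4, 4, 2))
  expect_equal(diceLoss(u, m), 0.5, tolerance = 1e-6)
  # three classes, uniform 1/3, class areas 4 and 12 of 16:
  # dice_c = (2*(1/3)*a + eps)/((16/3) + a + eps)
  g3 <- matrix(0L, 4, 4); g3[1, ] <- 1L; g3[2:4, ] <- 2L
  m3 <- LabelMask(g3, classNames = c("bg", "a", "b"))
  u3 <- array(1 / 3, c(4, 4, 3))
  d1 <- (2 * (1 / 3) * 4 + 1e-5) / (16 / 3 + 4 + 1e-5)
  d2 <- (2 * (1 / 3) * 12 + 1e-5) / (16 / 3 + 12 + 1e-5)
  expect_equal(diceLoss(u3, m3), 1 - (d1 + d2) / 2, tolerance = 1e-9)
})

test_that("batched dice gradient matches finite differences", {
  set.seed(1)
  logits <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  masks <- lapply(1:2, function(i)
    LabelMask(matrix(sample(0:2, 36, TRUE), 6, 6),
              classNames = c("bg", "a", "b")))
  dl <- dfseg:::.dice_loss_grad(logits, masks)
  set.seed(2)
  for (k in 1:6) {
    i <- sample(length(logits), 1)
    eps <- 1e-6
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    fd <- (dfseg:::.dice_loss_grad(lp, masks)$loss -
           dfseg:::.dice_loss_grad(lm, masks)$loss) / (2 * eps)
    expect_lt(abs(fd - dl$dlogits[i]) / max(1e-6, abs(fd)), 1e-4)
  }
})

test_that("DF supervision loss follows its closed form", {
  m <- generateBlobMasks(1, c(16, 16), nClasses = 3, seed = 5)[[1]]
  gt <- computeDF(m)
  fg <- maskGrid(m) > 0L
  expect_equal(dfLoss(dfVectors(gt), gt, fg), 0)
  # all-zero prediction against unit vectors: mean squared norm on the
  # non-boundary foreground is 1, boundary pixels contribute 0
  z <- dfVectors(gt) * 0
  nz <- dfNorm(gt) > 0
  expect_equal(dfLoss(z, gt, foreground = nz), 1, tolerance = 1e-12)
  # masking over all foreground dilutes by the boundary fraction
  expect_equal(dfLoss(z, gt, foreground = fg), sum(nz) / sum(fg),
               tolerance = 1e-12)
})

test_that("dice coefficient matches the overlap formula and is symmetric", {
  g1 <- matrix(0L, 4, 4); g1[1:2, 1:2] <- 1L
  g2 <- matrix(0L, 4, 4); g2[1:2, 2:3] <- 1L   # |A|=|B|=4, overlap 2
  a <- LabelMask(g1, c("bg", "x")); b <- LabelMask(g2, c("bg", "x"))
  expect_equal(diceCoefficient(a, b, 1L), 0.5)
  expect_equal(diceCoefficient(a, a, 1L), 1)
  g3 <- matrix(0L, 4, 4); g3[3:4, 3:4] <- 1L
  expect_equal(diceCoefficient(a, LabelMask(g3, c("bg", "x")), 1L), 0)
  # absent from both sides: defined as 1
  expect_equal(diceCoefficient(a, b, 9L), 1)
  masks <- generateBlobMasks(10, c(16, 16), 3, seed = 8)
  for (i in seq(1, 9, 2))
    expect_equal(diceCoefficient(masks[[i]], masks[[i + 1]], 1L),
                 diceCoefficient(masks[[i + 1]], masks[[i]], 1L))
})

test_that("hausdorff distance matches hand values and handles empties", {
  g1 <- matrix(0L, 5, 5); g1[1, 1] <- 1L
  g2 <- matrix(0L, 5, 5); g2[4, 5] <- 1L   # offset (3, 4) -> 5
  a <- LabelMask(g1, c("bg", "x")); b <- LabelMask(g2, c("bg", "x"))
  expect_equal(hausdorffDistance(a, b, 1L), 5)
  expect_equal(hausdorffDistance(a, a, 1L), 0)
  # anisotropic spacing scales the axes separately
  expect_equal(hausdorffDistance(a, b, 1L, spacing = c(2, 1)), sqrt(52))
  # empty side: an explicit missing value, not 0 or Inf
  expect_true(is.na(hausdorffDistance(a, LabelMask(matrix(0L, 5, 5),
                                                   c("bg", "x")), 1L)))
})

test_that("hausdorff fast path equals the exhaustive oracle on random pairs", {
  masks <- generateBlobMasks(100, c(32, 32), nClasses = 4, seed = 77)
  checked <- 0
  for (i in seq(1, 99, 2)) {
    for (lab in 1:3) {
      got <- hausdorffDistance(masks[[i]], masks[[i + 1]], lab)
      ref <- hausdorff_oracle(masks[[i]], masks[[i + 1]], lab)
      if (is.na(ref)) expect_true(is.na(got))
      else expect_equal(got, ref, tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 150)  # >= 50 pairs, three classes each
})

test_that("hausdorff agrees with pracma on the extracted boundary sets", {
  skip_if_not_installed("pracma")
  masks <- generateBlobMasks(20, c(24, 24), nClasses = 3, seed = 15)
  for (i in seq(1, 19, 2)) {
    A <- dfseg:::.class_boundary_coords(masks[[i]], 1L)
    B <- dfseg:::.class_boundary_coords(masks[[i + 1]], 1L)
    if (nrow(A) == 0 || nrow(B) == 0) next
    expect_equal(hausdorffDistance(masks[[i]], masks[[i + 1]], 1L),
                 pracma::hausdorff_dist(A, B), tolerance = 1e-12)
  }
})

test_that("evaluation report has one row per foreground class plus the mean", {
  ph <- small_phantom(frames = 2)
  rep <- evaluateMasks(ph$masks, ph$masks)
  expect_equal(nrow(rep), 7)           # 6 classes + mean
  expect_equal(rep$class[7], "mean")
  expect_true(all(rep$dice == 1))
  expect_true(all(rep$hausdorff == 0))
  expect_equal(attr(rep, "units"), "px")
  # with spacing the units switch to mm
  rep2 <- evaluateMasks(ph$masks, ph$masks, spacing = c(1.5, 1.5))
  expect_equal(attr(rep2, "units"), "mm")
  csv <- tempfile(fileext = ".csv")
  writeEvalReport(rep, csv = csv)
  expect_equal(read.csv(csv)$units[1], "px")
})

test_that("loss and metric agree on perfect predictions", {
  ph <- small_phantom(frames = 1)
  m <- ph$masks[[1]]
  C <- length(classNames(m))
  oh <- array(0, c(dim(maskGrid(m)), C))
  for (c in seq_len(C)) oh[, , c] <- maskGrid(m) == (c - 1L)
  expect_lt(diceLoss(oh, m), 1e-4)
  for (lab in 1:(C - 1))
    expect_equal(diceCoefficient(m, m, lab), 1)
})
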