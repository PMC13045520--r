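# Label masks, boundary extraction and directional fields.

test_that("LabelMask validates labels, names and spacing", {
  m <- LabelMask(matrix(0L, 4, 4))
  expect_s4_class(m, "LabelMask")
  expect_equal(length(classNames(m)), 7)  # speech default
  expect_error(LabelMask(matrix(9L, 2, 2), classNames = c("bg", "a")),
               "labels")
  expect_error(LabelMask(matrix(0L, 2, 2), pixelSpacing = c(-1, 1)),
               "positive")
  expect_equal(dim(m), c(4, 4))
})

test_that("boundaryPixels marks class pixels adjacent to a different label", {
  # all background: nothing to mark
  expect_false(any(boundaryPixels(LabelMask(matrix(0L, 5, 5)), 1L)))
  # uniform foreground 3x3: the grid edge counts as outside, so the ring
  # is boundary; the centre has only same-class in-grid neighbours
  b3 <- boundaryPixels(LabelMask(matrix(1L, 3, 3)), 1L)
  expect_false(b3[2, 2])
  expect_equal(sum(b3), 8)
  # a 2x2 grid is entirely boundary
  expect_true(all(boundaryPixels(LabelMask(matrix(1L, 2, 2)), 1L)))
  # isolated pixel is its own boundary
  g <- matrix(0L, 5, 5); g[3, 3] <- 1L
  b <- boundaryPixels(LabelMask(g), 1L)
  expect_equal(which(b), which(g == 1L))
  # background has no boundary
  expect_error(boundaryPixels(LabelMask(g), 0L), "background")
  # 8-connectivity marks diagonal contacts too
  g2 <- matrix(0L, 4, 4); g2[1:2, 1:2] <- 1L; g2[3, 3] <- 2L
  inner <- boundaryPixels(LabelMask(g2), 1L, connectivity = 8)
  expect_true(inner[2, 2])
})

test_that("computeDF matches its definition on hand-checkable masks", {
  # empty mask: all-zero field, no error
  z <- computeDF(LabelMask(matrix(0L, 4, 4)))
  expect_true(all(dfVectors(z) == 0))
  # uniform 5x5: ring is boundary (zero); centre ties at distance 2 to
  # four boundary pixels and the row-major rule picks the top one,
  # giving a vector pointing down from it: (dx, dy) = (0, +1)
  d <- dfVectors(computeDF(LabelMask(matrix(1L, 5, 5))))
  expect_equal(d[1, , ], matrix(0, 5, 2))
  expect_equal(d[3, 3, ], c(0, 1))
  # (2,2) ties between (1,2) and (2,1); row-major picks (1,2) above
  expect_equal(d[2, 2, ], c(0, 1))
  # filled disc: interior vectors are unit and point inward; exact match
  # with the exhaustive oracle
  g <- matrix(0L, 7, 7)
  for (r in 1:7) for (cc in 1:7)
    if ((r - 4)^2 + (cc - 4)^2 <= 9) g[r, cc] <- 1L
  m <- LabelMask(g)
  expect_equal(dfVectors(computeDF(m)), dfVectors(computeDFBruteForce(m)),
               tolerance = 0)
})

test_that("fast DF path equals the brute-force oracle on random blobs", {
  masks <- generateBlobMasks(100, c(32, 32), nClasses = 4, seed = 42)
  for (mode in c("per-class", "union-foreground")) {
    for (m in masks[1:25]) {
      expect_equal(dfVectors(computeDF(m, mode)),
                   dfVectors(computeDFBruteForce(m, mode)),
                   tolerance = 0)
    }
  }
  # the remaining masks in the cheaper default mode only
  for (m in masks[26:100])
    expect_equal(dfVectors(computeDF(m)),
                 dfVectors(computeDFBruteForce(m)), tolerance = 0)
})

test_that("DF norms are one on non-boundary foreground and zero elsewhere", {
  masks <- generateBlobMasks(20, c(24, 24), nClasses = 5, seed = 3)
  for (m in masks) {
    nrm <- dfNorm(computeDF(m))
    g <- maskGrid(m)
    zero <- g == 0L
    for (lab in setdiff(unique(as.vector(g)), 0L))
      zero <- zero | (boundaryPixels(m, lab) & g == lab)
    expect_true(all(abs(nrm[!zero] - 1) < 1e-6))
    expect_true(all(nrm[zero] == 0))
  }
})

test_that("DF is equivariant to integer translations and deterministic", {
  base <- generateBlobMasks(5, c(20, 20), nClasses = 3, seed = 9)
  for (m in base) {
    g <- maskGrid(m)
    big <- matrix(0L, 28, 28)
    big[5:24, 3:22] <- g
    d0 <- dfVectors(computeDF(m))
    d1 <- dfVectors(computeDF(LabelMask(big, classNames(m))))
    expect_equal(d1[5:24, 3:22, ], d0, tolerance = 0)
    # margins stay zero
    d1[5:24, 3:22, ] <- 0
    expect_true(all(d1 == 0))
    # bit-identical on repeat
    expect_identical(dfVectors(computeDF(m)), d0)
  }
})

test_that("mask and DF containers round-trip through files", {
  m <- generateBlobMasks(1, c(16, 16), nClasses = 4, seed = 1)[[1]]
  p <- tempfile(fileext = ".png")
  writeMaskPNG(m, p)
  expect_equal(maskGrid(readMaskPNG(p, classNames(m))), maskGrid(m))
  f <- computeDF(m)
  stem <- tempfile()
  writeDF(f, stem)
  expect_equal(dfVectors(readDF(stem)), dfVectors(f))
  skip_if_not_installed("RNifti")
  nf <- tempfile(fileext = ".nii.gz")
  writeMaskNIfTI(m, nf)
  expect_equal(maskGrid(readMaskNIfTI(nf, classNames(m))), maskGrid(m))
})
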