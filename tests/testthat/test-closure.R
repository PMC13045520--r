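# Velopharyngeal closure: frame detection, event extraction and matching.

test_that("closure detection responds to palate-wall contact only", {
  H <- 64; W <- 64
  open_m <- dfseg:::.phantom_mask(H, W, closed = FALSE)
  closed_m <- dfseg:::.phantom_mask(H, W, closed = TRUE)
  expect_equal(detectClosureFrame(LabelMask(open_m)), 0L)
  expect_equal(detectClosureFrame(LabelMask(closed_m)), 1L)
  # a 2 px air gap means no 8-adjacency anywhere
  pal <- which(open_m == 2L, arr.ind = TRUE)
  hed <- which(open_m == 1L, arr.ind = TRUE)
  dmin <- min(sqrt(outer(pal[, 1], hed[, 1], "-")^2 +
                   outer(pal[, 2], hed[, 2], "-")^2))
  expect_gte(dmin, 2)
  # no soft palate at all: open, with a warning
  expect_warning(r <- detectClosureFrame(LabelMask(matrix(0L, 8, 8))),
                 "soft-palate")
  expect_equal(r, 0L)
})

test_that("a posterior ROI excludes the anterior palate attachment", {
  m <- LabelMask(dfseg:::.phantom_mask(64, 64, closed = FALSE,
                                       anterior = TRUE))
  # anteriorly attached palate touches the head class somewhere
  expect_equal(detectClosureFrame(m), 1L)
  # restricted to the posterior third, the open port is detected as open
  roi <- c(1, 64, 45, 64)
  expect_equal(detectClosureFrame(m, roi = roi), 0L)
  mc <- LabelMask(dfseg:::.phantom_mask(64, 64, closed = TRUE,
                                        anterior = TRUE))
  expect_equal(detectClosureFrame(mc, roi = roi), 1L)
})

test_that("event extraction finds maximal runs as inclusive intervals", {
  ev <- extractEvents(c(0, 0, 1, 1, 0, 1, 0))
  expect_equal(ev, data.frame(start = c(2L, 5L), end = c(3L, 5L)))
  expect_equal(nrow(extractEvents(rep(0, 5))), 0)
  expect_equal(extractEvents(c(1, 1, 1)),
               data.frame(start = 0L, end = 2L))
  # rebuild round-trip is the identity on event lists
  set.seed(4)
  for (k in 1:20) {
    v <- as.integer(runif(30) > 0.6)
    ev <- extractEvents(v)
    expect_equal(eventsToSequence(ev, 30), v)
    expect_equal(extractEvents(eventsToSequence(ev, 30)), ev)
  }
})

test_that("event matching applies the one-frame endpoint tolerance", {
  gt <- data.frame(start = 5L, end = 10L)
  # extension by one frame at the start stays correct
  r <- matchEvents(gt, data.frame(start = 4L, end = 10L))
  expect_equal(r$correct, 1L)
  expect_equal(r$additional + r$merged + r$missed, 0L)
  # extension at the end too
  expect_equal(matchEvents(gt, data.frame(start = 5L, end = 11L))$correct, 1L)
  # two frames off is no longer correct but is still matched (not
  # additional, not missed)
  r2 <- matchEvents(gt, data.frame(start = 3L, end = 10L))
  expect_equal(r2$correct, 0L)
  expect_equal(r2$additional, 0L)
  expect_equal(r2$missed, 0L)
  # one prediction spanning two GT events is merged
  r3 <- matchEvents(data.frame(start = c(5L, 15L), end = c(10L, 20L)),
                    data.frame(start = 5L, end = 20L))
  expect_equal(r3$merged, 1L)
  expect_equal(r3$correct, 0L)
  expect_equal(r3$additional, 0L)
  expect_equal(r3$missed, 0L)
  expect_equal(r3$total_pred, 1L)
  # empty sides
  r4 <- matchEvents(gt, data.frame(start = integer(0), end = integer(0)))
  expect_equal(r4$missed, 1L)
  r5 <- matchEvents(data.frame(start = integer(0), end = integer(0)),
                    data.frame(start = 3L, end = 4L))
  expect_equal(r5$additional, 1L)
  # malformed lists are rejected
  expect_error(matchEvents(data.frame(start = c(1L, 3L), end = c(4L, 6L)),
                           gt), "overlapping")
})

test_that("matching a list against itself is all-correct", {
  set.seed(6)
  for (k in 1:10) {
    v <- as.integer(runif(40) > 0.65)
    ev <- extractEvents(v)
    r <- matchEvents(ev, ev)
    expect_equal(r$correct, nrow(ev))
    expect_equal(r$additional + r$merged + r$missed, 0L)
  }
})

test_that("the total_pred decomposition holds on randomized event lists", {
  set.seed(8)
  for (k in 1:30) {
    gt <- extractEvents(as.integer(runif(50) > 0.7))
    pr <- extractEvents(as.integer(runif(50) > 0.7))
    r <- matchEvents(gt, pr)
    # independent overlap matrix
    if (nrow(pr) && nrow(gt)) {
      ov <- sapply(seq_len(nrow(gt)), function(j)
        sapply(seq_len(nrow(pr)), function(i)
          max(pr$start[i], gt$start[j]) <= min(pr$end[i], gt$end[j])))
      ov <- matrix(ov, nrow(pr))
      matched1 <- sum(rowSums(ov) == 1)
    } else matched1 <- 0
    expect_equal(r$total_pred, matched1 + r$additional + r$merged)
    expect_lte(r$correct, max(0, matched1))
    expect_lte(r$correct, nrow(gt))
  }
})

test_that("frame accuracy partitions disagreements into FP and FN", {
  a <- ClosureSequence(c(0, 1, 1, 0), "s")
  expect_equal(frameAccuracy(a, a),
               c(accuracy = 100, false_positive = 0, false_negative = 0))
  r <- frameAccuracy(rep(0, 10), rep(1, 10))
  expect_equal(unname(r), c(0, 100, 0))
  v <- c(rep(1, 50), rep(0, 50))
  w <- v; w[100] <- 1
  r2 <- frameAccuracy(v, w)
  expect_equal(unname(r2["accuracy"]), 99)
  expect_equal(sum(r2), 100)
  set.seed(2)
  for (k in 1:10) {
    g <- as.integer(runif(37) > 0.5)
    p <- as.integer(runif(37) > 0.5)
    expect_equal(sum(frameAccuracy(g, p)), 100)
  }
  expect_error(frameAccuracy(c(0, 1), c(0, 1, 1)), "length")
})

test_that("closure sequences round-trip through CSV", {
  s <- ClosureSequence(c(0, 1, 1, 0, 1), "s1")
  p <- tempfile(fileext = ".csv")
  writeClosureCSV(s, p)
  r <- readClosureCSV(p, "s1")
  expect_equal(closureLabels(r), closureLabels(s))
  expect_equal(seriesId(r), "s1")
})
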