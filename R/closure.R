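## Velopharyngeal closure analysis: frame-level detection from masks,
## event extraction, and event matching against ground truth with the
## one-frame endpoint tolerance (correct / additional / merged / missed).

#' Detect velopharyngeal closure in one frame
#'
#' A frame is closed (1) iff any soft-palate pixel is 8-adjacent to a head
#' pixel inside the region of interest. The ROI exists because in real
#' anatomy the soft palate is permanently attached to the hard palate
#' (head class) anteriorly; a posterior ROI restricts the test to the
#' velopharyngeal port.
#'
#' @param mask a [LabelMask-class] using the speech label set.
#' @param roi optional c(rowMin, rowMax, colMin, colMax) (1-based,
#'   inclusive); default is the full frame.
#' @param palateClass,headClass integer ids of the two classes (defaults 2
#'   and 1, the speech convention).
#' @return integer 0/1. A frame with no soft-palate pixel at all returns 0
#'   with a warning.
#' @export
detectClosureFrame <- function(mask, roi = NULL, palateClass = 2L,
                               headClass = 1L) {
  g <- maskGrid(mask)
  if (!is.null(roi)) {
    g <- g[max(1, roi[1]):min(nrow(g), roi[2]),
           max(1, roi[3]):min(ncol(g), roi[4]), drop = FALSE]
  }
  pal <- g == palateClass
  if (!any(maskGrid(mask) == palateClass)) {
    warning("mask contains no soft-palate pixels; reporting open")
    return(0L)
  }
  if (!any(pal)) return(0L)
  hed <- g == headClass
  H <- nrow(g); W <- ncol(g)
  near <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(H, H + dr)
    rt <- max(1, 1 - dr):min(H, H - dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    ct <- max(1, 1 - dc):min(W, W - dc)
    near[rt, ct] <- near[rt, ct] | hed[rs, cs]
  }
  as.integer(any(pal & near))
}

#' Closure sequence of a series of masks
#' @param masks list of [LabelMask-class] frames.
#' @param roi,palateClass,headClass passed to [detectClosureFrame()].
#' @param seriesId identifier for the resulting sequence.
#' @return A [ClosureSequence-class].
#' @export
detectClosureSequence <- function(masks, roi = NULL, palateClass = 2L,
                                  headClass = 1L, seriesId = "series") {
  ClosureSequence(vapply(masks, detectClosureFrame, integer(1), roi = roi,
                         palateClass = palateClass, headClass = headClass),
                  seriesId)
}

#' Extract closure events from a frame sequence
#'
#' Maximal runs of consecutive closed frames become inclusive intervals.
#' Frame indices are 0-based, matching the closure CSV convention.
#'
#' @param seq a [ClosureSequence-class] or 0/1 vector.
#' @return data.frame with integer columns `start`, `end` (0-based,
#'   inclusive), sorted and disjoint; zero rows when never closed.
#' @export
extractEvents <- function(seq) {
  v <- if (is(seq, "ClosureSequence")) closureLabels(seq) else as.integer(seq)
  if (!length(v) || !any(v == 1L))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L)
}

#' Rebuild a 0/1 frame sequence from an event table
#' @param events data.frame with `start`, `end` (0-based inclusive).
#' @param nFrames total frame count.
#' @return integer 0/1 vector of length `nFrames`.
#' @export
eventsToSequence <- function(events, nFrames) {
  v <- integer(nFrames)
  for (k in seq_len(nrow(events)))
    v[(events$start[k] + 1L):(events$end[k] + 1L)] <- 1L
  v
}

.check_events <- function(ev, what) {
  if (!nrow(ev)) return(invisible())
  if (any(ev$start > ev$end)) stop(what, ": event start after end")
  o <- order(ev$start)
  if (nrow(ev) > 1 && any(ev$start[o][-1] <= ev$end[o][-nrow(ev)]))
    stop(what, ": overlapping events within one list")
  invisible()
}

#' Match predicted closure events against ground truth
#'
#' A predicted event overlapping exactly one GT event is a candidate
#' match; it is *correct* when both endpoints lie within one frame of the
#' GT endpoints. A predicted event overlapping two or more GT events is
#' *merged*; one overlapping none is *additional*. A GT event overlapped
#' by no prediction is *missed* (GT events covered only by a merged
#' prediction are neither correct nor missed). Overlap means intersecting
#' inclusive intervals, with no tolerance; the one-frame tolerance applies
#' only to the endpoint test.
#'
#' @param gt,pred data.frames with `start`, `end` columns (disjoint,
#'   sorted events as from [extractEvents()]).
#' @return list of class `"EventMatchReport"` with counts `total_pred`,
#'   `correct`, `additional`, `merged`, `missed`.
#' @export
matchEvents <- function(gt, pred) {
  .check_events(gt, "gt")
  .check_events(pred, "pred")
  ng <- nrow(gt); np <- nrow(pred)
  ov <- matrix(FALSE, np, ng)
  if (np && ng)
    for (i in seq_len(np))
      ov[i, ] <- pred$start[i] <= gt$end & pred$end[i] >= gt$start
  novP <- if (ng) rowSums(ov) else rep(0L, np)
  correct <- 0L
  for (i in seq_len(np)) {
    if (np && ng && novP[i] == 1L) {
      j <- which(ov[i, ])
      if (abs(pred$start[i] - gt$start[j]) <= 1L &&
          abs(pred$end[i] - gt$end[j]) <= 1L)
        correct <- correct + 1L
    }
  }
  additional <- sum(novP == 0L)
  merged <- sum(novP >= 2L)
  missed <- if (np) sum(colSums(ov) == 0L) else ng
  structure(list(total_pred = np, correct = correct,
                 additional = as.integer(additional),
                 merged = as.integer(merged),
                 missed = as.integer(missed)),
            class = "EventMatchReport")
}

#' @export
print.EventMatchReport <- function(x, ...) {
  cat(sprintf("closure events: %d predicted | %d correct, %d additional, %d merged, %d missed\n",
              x$total_pred, x$correct, x$additional, x$merged, x$missed))
  invisible(x)
}

#' Frame-level closure classification accuracy
#'
#' @param gt,pred [ClosureSequence-class] objects (or 0/1 vectors) of
#'   equal length.
#' @return named numeric: `accuracy`, `false_positive` (predicted closed,
#'   GT open) and `false_negative`, all as percentages of the frame count;
#'   the three always sum to 100.
#' @export
frameAccuracy <- function(gt, pred) {
  g <- if (is(gt, "ClosureSequence")) closureLabels(gt) else as.integer(gt)
  p <- if (is(pred, "ClosureSequence")) closureLabels(pred) else as.integer(pred)
  if (length(g) != length(p)) stop("sequence length mismatch")
  n <- length(g)
  c(accuracy = 100 * sum(g == p) / n,
    false_positive = 100 * sum(p == 1L & g == 0L) / n,
    false_negative = 100 * sum(p == 0L & g == 1L) / n)
}

#' Write an event-match report as CSV/JSON
#' @param report an `"EventMatchReport"`.
#' @param csv,json optional output paths.
#' @return the report, invisibly.
#' @export
writeEventReport <- function(report, csv = NULL, json = NULL) {
  d <- data.frame(total = report$total_pred, correct = report$correct,
                  additional = report$additional, merged = report$merged,
                  missed = report$missed)
  if (!is.null(csv)) write.csv(d, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE)
  invisible(report)
}
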