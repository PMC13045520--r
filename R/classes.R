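## Core S4 data currencies: label masks, directional fields, closure traces.

#' LabelMask: an integer-labelled segmentation grid
#'
#' One frame's segmentation: an H x W integer matrix with values in
#' 0..C-1 where 0 is background, plus the ordered class names and optional
#' pixel spacing in millimetres (row, column).
#'
#' @slot grid integer matrix, values in `0..length(classNames)-1`.
#' @slot classNames character vector of C class names; `classNames[1]`
#'   names label 0 (background).
#' @slot pixelSpacing numeric of length 0 (unknown) or 2: (row_mm, col_mm).
#' @export
setClass("LabelMask",
  representation(grid = "matrix", classNames = "character",
                 pixelSpacing = "numeric"),
  prototype(pixelSpacing = numeric(0)))

setValidity("LabelMask", function(object) {
  g <- object@grid
  if (!is.numeric(g) && !is.integer(g)) return("grid must be numeric")
  if (any(g != floor(g))) return("grid must contain integer labels")
  C <- length(object@classNames)
  if (C < 1) return("classNames must be non-empty")
  if (length(g) && (min(g) < 0 || max(g) > C - 1))
    return(sprintf("labels must lie in [0, %d]", C - 1))
  if (!length(object@pixelSpacing) %in% c(0L, 2L))
    return("pixelSpacing must have length 0 or 2")
  if (length(object@pixelSpacing) == 2L && any(object@pixelSpacing <= 0))
    return("pixelSpacing must be positive")
  TRUE
})

#' Construct a LabelMask
#'
#' @param grid integer matrix of labels (0 = background).
#' @param classNames ordered class names; defaults to the speech MRI set
#'   when the labels fit in 0..6, otherwise `"class<k>"` placeholders.
#' @param pixelSpacing optional numeric(2), (row_mm, col_mm).
#' @return A [LabelMask-class] object.
#' @examples
#' m <- LabelMask(matrix(0L, 4, 4))
#' maskGrid(m)
#' @export
LabelMask <- function(grid, classNames = NULL, pixelSpacing = numeric(0)) {
  storage.mode(grid) <- "integer"
  if (is.null(classNames)) {
    mx <- if (length(grid)) max(grid) else 0L
    classNames <- if (mx <= 6L) .speech_classes
                  else c("background", paste0("class", seq_len(mx)))
  }
  new("LabelMask", grid = grid, classNames = classNames,
      pixelSpacing = as.numeric(pixelSpacing))
}

#' @describeIn LabelMask the raw integer grid
#' @param x a `LabelMask`
#' @export
maskGrid <- function(x) x@grid

#' Class names of a mask or field object
#' @param x a `LabelMask`
#' @return character vector of class names.
#' @export
classNames <- function(x) x@classNames

#' Pixel spacing of a mask
#' @param x a `LabelMask`
#' @return numeric(2) (row_mm, col_mm) or numeric(0) if unknown.
#' @export
pixelSpacing <- function(x) x@pixelSpacing

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@grid)
  present <- sort(unique(as.vector(object@grid)))
  cat(sprintf("LabelMask %dx%d, %d classes (%s)\n", d[1], d[2],
              length(object@classNames),
              paste(object@classNames[present + 1], collapse = ", ")))
  if (length(object@pixelSpacing) == 2)
    cat(sprintf("  spacing: %.3f x %.3f mm\n",
                object@pixelSpacing[1], object@pixelSpacing[2]))
})

setMethod("dim", "LabelMask", function(x) dim(x@grid))

#' DirectionalField: per-pixel boundary direction vectors
#'
#' An H x W x 2 array; channel 1 holds dx (column) and channel 2 dy (row)
#' components, in 0-based pixel-centre coordinates. On non-boundary
#' foreground pixels the vector is unit-norm and points from the nearest
#' boundary pixel toward the pixel; elsewhere it is exactly (0, 0).
#'
#' @slot vectors numeric array H x W x 2.
#' @export
setClass("DirectionalField", representation(vectors = "array"))

setValidity("DirectionalField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 3 || d[3] != 2) return("vectors must be H x W x 2")
  TRUE
})

#' Construct a DirectionalField
#' @param vectors numeric H x W x 2 array, channels (dx, dy).
#' @return A [DirectionalField-class] object.
#' @export
DirectionalField <- function(vectors) new("DirectionalField", vectors = vectors)

#' @describeIn DirectionalField the raw H x W x 2 array (channels dx, dy)
#' @param x a `DirectionalField`
#' @export
dfVectors <- function(x) x@vectors

setMethod("show", "DirectionalField", function(object) {
  d <- dim(object@vectors)
  n <- sum(sqrt(object@vectors[, , 1]^2 + object@vectors[, , 2]^2) > 0.5)
  cat(sprintf("DirectionalField %dx%d (%d non-zero vectors)\n", d[1], d[2], n))
})

setMethod("dim", "DirectionalField", function(x) dim(x@vectors))

#' ClosureSequence: per-frame velopharyngeal closure labels
#'
#' An ordered binary trace over the frames of one series: 1 = the
#' velopharyngeal port is closed (soft palate in contact with the posterior
#' pharyngeal wall), 0 = open.
#'
#' @slot labels integer vector of 0/1 values, one per frame.
#' @slot seriesId character identifier of the series.
#' @export
setClass("ClosureSequence",
  representation(labels = "integer", seriesId = "character"))

setValidity("ClosureSequence", function(object) {
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    return("labels must be 0/1")
  TRUE
})

#' Construct a ClosureSequence
#' @param labels vector of 0/1 frame labels.
#' @param seriesId series identifier.
#' @return A [ClosureSequence-class] object.
#' @export
ClosureSequence <- function(labels, seriesId = "series") {
  new("ClosureSequence", labels = as.integer(labels),
      seriesId = as.character(seriesId))
}

#' @describeIn ClosureSequence the 0/1 frame labels
#' @param x a `ClosureSequence`
#' @export
closureLabels <- function(x) x@labels

#' @describeIn ClosureSequence the series identifier
#' @param x a `ClosureSequence`
#' @export
seriesId <- function(x) x@seriesId

setMethod("show", "ClosureSequence", function(object) {
  cat(sprintf("ClosureSequence '%s': %d frames, %d closed\n",
              object@seriesId, length(object@labels), sum(object@labels)))
})

setMethod("length", "ClosureSequence", function(x) length(x@labels))
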