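## File I/O: grayscale PNG frames, label-mask PNGs (pixel value = class id),
## single-frame NIfTI masks, and directional-field containers (raw float64
## array plus a JSON sidecar recording shape and channel convention).

#' Write a label mask as an 8-bit grayscale PNG
#'
#' The pixel value stores the class id directly (0..255), so the file
#' round-trips exactly for label sets of up to 256 classes.
#'
#' @param mask a [LabelMask-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  g <- maskGrid(mask)
  if (max(g) > 255L) stop("PNG mask storage supports at most 256 classes")
  png::writePNG(g / 255, target = path)
  invisible(path)
}

#' Read a label mask from an 8-bit grayscale PNG
#'
#' @param path PNG written by [writeMaskPNG()].
#' @param classNames optional class names (defaults as in [LabelMask()]).
#' @param pixelSpacing optional numeric(2) spacing in mm.
#' @return A [LabelMask-class].
#' @export
readMaskPNG <- function(path, classNames = NULL, pixelSpacing = numeric(0)) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  LabelMask(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)),
            classNames = classNames, pixelSpacing = pixelSpacing)
}

#' Write a grayscale image frame as PNG
#' @param image numeric matrix; values are clamped to [0, 1].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Read a grayscale image frame from PNG
#' @param path PNG file path.
#' @return numeric matrix in [0, 1].
#' @export
readImagePNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

#' Write a label mask as single-frame NIfTI
#'
#' Requires the RNifti package. Pixel spacing, when present, is stored in
#' the NIfTI header.
#'
#' @param mask a [LabelMask-class].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeMaskNIfTI <- function(mask, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writeMaskNIfTI requires the RNifti package")
  sp <- pixelSpacing(mask)
  img <- RNifti::asNifti(maskGrid(mask))
  if (length(sp) == 2) RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label mask from single-frame NIfTI
#' @param path `.nii`/`.nii.gz` path.
#' @param classNames optional class names.
#' @return A [LabelMask-class] (spacing taken from the header).
#' @export
readMaskNIfTI <- function(path, classNames = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("readMaskNIfTI requires the RNifti package")
  img <- RNifti::readNifti(path)
  g <- matrix(as.integer(round(as.vector(img))), dim(img)[1], dim(img)[2])
  sp <- tryCatch(RNifti::pixdim(img)[1:2], error = function(e) numeric(0))
  if (length(sp) == 2 && all(is.finite(sp)) && all(sp > 0) &&
      !all(sp == 1)) sp <- as.numeric(sp) else sp <- numeric(0)
  LabelMask(g, classNames = classNames, pixelSpacing = sp)
}

#' Write a directional field to a portable container
#'
#' Writes `<path>.bin` (float64, column-major, little-endian) and
#' `<path>.json` (shape and channel convention).
#'
#' @param field a [DirectionalField-class].
#' @param path output path stem (no extension).
#' @return `path`, invisibly.
#' @export
writeDF <- function(field, path) {
  v <- dfVectors(field)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(v), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(shape = dim(v), order = "column-major",
         channels = c("dx (column)", "dy (row)"),
         dtype = "float64", endian = "little"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a directional field written by [writeDF()]
#' @param path path stem used at write time.
#' @return A [DirectionalField-class].
#' @export
readDF <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  DirectionalField(array(v, meta$shape))
}

#' Write a closure sequence as a two-column CSV
#' @param seq a [ClosureSequence-class].
#' @param path output CSV path (columns `frame_index`, `closed`).
#' @return `path`, invisibly.
#' @export
writeClosureCSV <- function(seq, path) {
  write.csv(data.frame(frame_index = seq_along(closureLabels(seq)) - 1L,
                       closed = closureLabels(seq)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a closure sequence from a two-column CSV
#' @param path CSV written by [writeClosureCSV()].
#' @param seriesId series identifier for the result.
#' @return A [ClosureSequence-class].
#' @export
readClosureCSV <- function(path, seriesId = "series") {
  d <- read.csv(path)
  ClosureSequence(d$closed[order(d$frame_index)], seriesId)
}
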