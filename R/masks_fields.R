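## Boundary extraction and ground-truth directional fields.
##
## A class boundary pixel carries the class label and has a neighbour
## (4-connectivity by default) with a different label; pixels at the grid
## edge count the outside as background. The directional field assigns
## every non-boundary foreground pixel the unit vector (p - b)/|p - b|
## where b is its nearest boundary pixel under Euclidean distance; ties
## are broken by the row-major smallest b. Boundary and background pixels
## get exactly (0, 0).

#' Boundary pixels of one anatomical class
#'
#' @param mask a [LabelMask-class].
#' @param label integer class id (> 0); background has no boundary.
#' @param connectivity 4 (default) or 8: which neighbours can differ.
#' @return logical H x W matrix, TRUE on boundary pixels of `label`.
#' @examples
#' g <- matrix(0L, 5, 5); g[3, 3] <- 1L
#' boundaryPixels(LabelMask(g), 1L)[3, 3]
#' @export
boundaryPixels <- function(mask, label, connectivity = 4L) {
  stopifnot(is(mask, "LabelMask"))
  label <- as.integer(label)
  if (label == 0L) stop("background has no boundary")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  boundary_cpp(maskGrid(mask), label, as.integer(connectivity))
}

#' Ground-truth directional field of a label mask
#'
#' For every foreground pixel p that is not itself a boundary pixel, the
#' field holds (p - b)/|p - b| with b the nearest boundary pixel; the
#' vector points from the boundary toward the pixel. In `"per-class"` mode
#' (default) each pixel is referred to its own class's boundary; in
#' `"union-foreground"` mode to the union of all class boundaries.
#'
#' @param mask a [LabelMask-class].
#' @param mode `"per-class"` or `"union-foreground"`.
#' @param connectivity boundary connectivity, 4 (default) or 8.
#' @return A [DirectionalField-class]; channels are (dx, dy).
#' @seealso [computeDFBruteForce()] for the exhaustive reference
#'   implementation with the identical contract.
#' @export
computeDF <- function(mask, mode = c("per-class", "union-foreground"),
                      connectivity = 4L) {
  stopifnot(is(mask, "LabelMask"))
  mode <- match.arg(mode)
  v <- df_from_mask_cpp(maskGrid(mask), mode == "per-class",
                        as.integer(connectivity))
  DirectionalField(v)
}

#' Exhaustive-scan directional field (reference implementation)
#'
#' Same contract as [computeDF()], implemented in plain R by scanning all
#' boundary pixels for every foreground pixel. Intended as an independent
#' oracle for modest mask sizes (<= 128 x 128).
#'
#' @inheritParams computeDF
#' @return A [DirectionalField-class].
#' @export
computeDFBruteForce <- function(mask,
                                mode = c("per-class", "union-foreground"),
                                connectivity = 4L) {
  stopifnot(is(mask, "LabelMask"))
  mode <- match.arg(mode)
  g <- maskGrid(mask)
  H <- nrow(g); W <- ncol(g)
  out <- array(0, c(H, W, 2))
  labs <- sort(setdiff(unique(as.vector(g)), 0L))
  if (!length(labs)) return(DirectionalField(out))

  bnd_of <- function(lab) boundary_list_r(g, lab, connectivity)

  if (mode == "per-class") {
    groups <- lapply(labs, function(lab) {
      b <- bnd_of(lab)
      px <- which(g == lab, arr.ind = TRUE)
      list(bnd = b, px = px)
    })
  } else {
    ball <- do.call(rbind, lapply(labs, bnd_of))
    ball <- ball[order(ball[, 1], ball[, 2]), , drop = FALSE]
    px <- which(g > 0L, arr.ind = TRUE)
    groups <- list(list(bnd = ball, px = px))
  }

  for (grp in groups) {
    b <- grp$bnd
    if (!nrow(b)) next
    bkey <- paste(b[, 1], b[, 2])
    for (k in seq_len(nrow(grp$px))) {
      pr <- grp$px[k, 1]; pc <- grp$px[k, 2]
      if (paste(pr, pc) %in% bkey) next
      d2 <- (pr - b[, 1])^2 + (pc - b[, 2])^2
      j <- which.min(d2)  # first minimum = row-major smallest b
      dr <- pr - b[j, 1]; dc <- pc - b[j, 2]
      nrm <- sqrt(dr^2 + dc^2)
      out[pr, pc, 1] <- dc / nrm
      out[pr, pc, 2] <- dr / nrm
    }
  }
  DirectionalField(out)
}

# boundary pixels of `lab` in row-major order, pure R (no C++ reuse so the
# oracle path stays independent of the fast path)
boundary_list_r <- function(g, lab, connectivity = 4L) {
  H <- nrow(g); W <- ncol(g)
  pad <- matrix(-1L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- g
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  differs <- matrix(FALSE, H, W)
  for (s in shifts) {
    nb <- pad[2:(H + 1) + s[1], 2:(W + 1) + s[2]]
    differs <- differs | (nb != ctr)
  }
  hit <- which((g == lab) & differs, arr.ind = TRUE)
  hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
}

#' Per-pixel norms of a directional field
#' @param field a [DirectionalField-class].
#' @return numeric H x W matrix of Euclidean norms.
#' @export
dfNorm <- function(field) {
  v <- dfVectors(field)
  sqrt(v[, , 1]^2 + v[, , 2]^2)
}
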