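# Binary morphology with a disk structuring element.
#
# Dilation is computed as the union of the mask shifted by every offset of
# the disk; erosion is the complement-dual. This is exact and fast enough at
# megapixel scale for the small radii used here (a radius-3 disk has 29
# offsets). A brute-force max/min-filter oracle lives in the test suite.

#' Integer offsets of a rasterised disk
#'
#' All (dy, dx) lattice offsets with dy^2 + dx^2 <= r^2.
#'
#' @param r Disk radius in pixels (positive integer).
#' @return Two-column integer matrix of offsets.
#' @export
disk_offsets <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 1L)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  as.matrix(g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE])
}

.shift_or <- function(acc, mask, dy, dx) {
  h <- nrow(mask); w <- ncol(mask)
  ys <- max(1, 1 + dy):min(h, h + dy)   # destination rows
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) < 1 || length(xs) < 1) return(acc)
  acc[ys, xs] <- acc[ys, xs] | mask[ys - dy, xs - dx]
  acc
}

#' Binary dilation by a disk
#' @param mask Logical matrix.
#' @param r Disk radius in pixels.
#' @return Logical matrix of the same dimensions.
#' @export
binary_dilate <- function(mask, r = 3L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  off <- disk_offsets(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- .shift_or(out, mask, off[i, 1], off[i, 2])
  out
}

#' Binary erosion by a disk
#'
#' Dual of dilation; pixels outside the image border are treated as
#' background, so erosion shrinks the mask at the frame edge.
#' @inheritParams binary_dilate
#' @export
binary_erode <- function(mask, r = 3L) {
  !binary_dilate(!mask, r)
}

#' Morphological closing by a disk
#'
#' Dilation followed by erosion with the same disk element: fills gaps
#' (holes, cracks) smaller than the disk while leaving larger openings
#' intact. Closing is extensive (`mask` is a subset of the result) and
#' idempotent.
#'
#' @inheritParams binary_dilate
#' @export
close_mask <- function(mask, r = 3L) {
  binary_erode(binary_dilate(mask, r), r)
}

# class-mask integer codes
MASK_RED <- 1L
MASK_BLUE <- 2L
MASK_WHITE <- 3L

#' Close the red and blue regions of a class mask
#'
#' Applies morphological closing independently to the red region and then to
#' the blue region of a red/blue/white class mask. A pixel claimed by both
#' closed regions keeps its pre-closing label (closing fills gaps; it never
#' reassigns a confidently labelled pixel). Pixels claimed by neither stay
#' white.
#'
#' @param labels Integer matrix over codes 1 = red, 2 = blue, 3 = white.
#' @param r Disk radius in pixels (default 3: gaps of smaller radius fill).
#' @return Integer matrix of the same codes.
#' @export
close_regions <- function(labels, r = 3L) {
  stopifnot(is.matrix(labels))
  red <- labels == MASK_RED
  blue <- labels == MASK_BLUE
  cred <- close_mask(red, r)
  cblue <- close_mask(blue, r)
  out <- labels                       # default: pre-closing label
  out[cred & !cblue] <- MASK_RED
  out[cblue & !cred] <- MASK_BLUE
  # both claim it -> pre-closing label already in `out`
  out
}
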