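# sRGB <-> CIE L*a*b* conversion (D65 illuminant, 2 degree observer).
# Implemented from the IEC 61966-2-1 sRGB decoding and the CIE Lab
# definition; grDevices::convertColor is used only as a test oracle.

# sRGB (linear) -> XYZ matrix, D65 white
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
# white point taken as the image of RGB (1,1,1) under the matrix above, so
# that pure white maps to exactly (L*, a*, b*) = (100, 0, 0); this differs
# from the nominal D65 (0.95047, 1, 1.08883) only in the 7th decimal
.WHITE_D65 <- rowSums(.M_RGB2XYZ)

.srgb_decode <- function(c) {
  # gamma expansion: 8-bit channel already scaled to [0,1]
  lo <- c <= 0.04045
  out <- ((c + 0.055) / 1.055)^2.4
  out[lo] <- c[lo] / 12.92
  out
}

.srgb_encode <- function(c) {
  lo <- c <= 0.0031308
  out <- 1.055 * c^(1 / 2.4) - 0.055
  out[lo] <- 12.92 * c[lo]
  out
}

.lab_f <- function(t) {
  d <- 6 / 29
  lo <- t <= d^3
  out <- t^(1 / 3)
  out[lo] <- t[lo] / (3 * d^2) + 4 / 29
  out
}

.lab_finv <- function(t) {
  d <- 6 / 29
  lo <- t <= d
  out <- t^3
  out[lo] <- 3 * d^2 * (t[lo] - 4 / 29)
  out
}

# core: n x 3 matrix of sRGB in [0,1] -> n x 3 matrix of (L, a, b)
srgb_to_lab_mat <- function(rgb) {
  lin <- .srgb_decode(rgb)
  xyz <- lin %*% t(.M_RGB2XYZ)
  fx <- .lab_f(xyz[, 1] / .WHITE_D65[1])
  fy <- .lab_f(xyz[, 2] / .WHITE_D65[2])
  fz <- .lab_f(xyz[, 3] / .WHITE_D65[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# inverse: n x 3 (L, a, b) -> n x 3 sRGB in [0,1], clipped to gamut
lab_to_srgb_mat <- function(lab) {
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(.lab_finv(fx) * .WHITE_D65[1],
               .lab_finv(fy) * .WHITE_D65[2],
               .lab_finv(fz) * .WHITE_D65[3])
  lin <- xyz %*% t(.M_XYZ2RGB)
  rgb <- .srgb_encode(pmin(pmax(lin, 0), 1))
  pmin(pmax(rgb, 0), 1)
}

#' Convert an 8-bit sRGB image to CIE L*a*b*
#'
#' Standard sRGB decoding (gamma expansion, linear transform to XYZ) followed
#' by the CIE L*a*b* transform under the D65 illuminant and 2 degree observer.
#' Lightness L* lies in \[0, 100\] for in-gamut input; a* and b* are the
#' signed green--red and blue--yellow opponent axes on which the red/blue
#' stain clustering operates.
#'
#' @param img An `H x W x 3` (or `H x W x 4`; alpha is dropped) numeric array
#'   of 8-bit sRGB values in \[0, 255\].
#' @return A `lab_image`: list with `H x W` matrices `L`, `a`, `b`.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_lab(px)$L
#' @export
rgb_to_lab <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("expected an H x W x C array of 8-bit sRGB values")
  nc <- dim(img)[3]
  if (nc == 4L) img <- img[, , 1:3, drop = FALSE]   # drop alpha
  else if (nc != 3L)
    stop("expected 3 colour channels (grayscale input is not supported: ",
         "the segmentation is colour-based)")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("channel values must lie in [0, 255]")
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3])) / 255
  lab <- srgb_to_lab_mat(rgb)
  structure(list(L = matrix(lab[, 1], h, w),
                 a = matrix(lab[, 2], h, w),
                 b = matrix(lab[, 3], h, w)),
            class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf("<lab_image %d x %d>  L* range [%.1f, %.1f]\n",
              nrow(x$L), ncol(x$L), min(x$L), max(x$L)))
  invisible(x)
}
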