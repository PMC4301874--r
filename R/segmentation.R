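# Collagen quantification from a trichrome micrograph:
# Lab transform -> k-means on (a*, b*) -> red/blue labelling -> uniform
# lightness mask -> morphological closing -> percent collagen.

#' Segmentation configuration
#'
#' Collects every tunable of the collagen segmentation so a run can record
#' exactly how it was produced.
#'
#' @param lightness_threshold L* value above which a pixel is masked as
#'   white, in (0, 100]. Default 85: masks near-white background and lumen
#'   without eating pale collagen. The same threshold must be used for every
#'   image of a run (uniformity is part of the contract).
#' @param closing_radius_px Disk radius of the morphological closing
#'   (default 3: gaps of radius < 3 px fill).
#' @param kmeans_seed,kmeans_restarts,kmeans_tol k-means determinism and
#'   convergence controls (defaults 0, 5, 1e-6).
#' @param mask_before_cluster If `TRUE`, white pixels are excluded from the
#'   clustering input (non-default alternative; the default clusters all
#'   pixels and applies the white mask as an override afterwards, matching
#'   the order cluster -> mask -> close).
#' @param denominator `"image"` (default: percent collagen over the entire
#'   image area, white included) or `"tissue"` (over non-white pixels only;
#'   explicit non-default option, since the literal rule makes the percent
#'   depend on tissue coverage).
#' @return A `seg_config` list.
#' @export
seg_config <- function(lightness_threshold = 85,
                       closing_radius_px = 3L,
                       kmeans_seed = 0L,
                       kmeans_restarts = 5L,
                       kmeans_tol = 1e-6,
                       mask_before_cluster = FALSE,
                       denominator = c("image", "tissue")) {
  denominator <- match.arg(denominator)
  stopifnot(lightness_threshold > 0, lightness_threshold <= 100,
            closing_radius_px >= 1, kmeans_restarts >= 1, kmeans_tol > 0)
  structure(list(lightness_threshold = lightness_threshold,
                 closing_radius_px = as.integer(closing_radius_px),
                 kmeans_seed = as.integer(kmeans_seed),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 kmeans_tol = kmeans_tol,
                 mask_before_cluster = mask_before_cluster,
                 denominator = denominator),
            class = "seg_config")
}

#' High-lightness (white) mask
#'
#' A pixel is white iff L* exceeds the uniform lightness threshold.
#'
#' @param lab A `lab_image`.
#' @param cfg A [seg_config()].
#' @return Logical matrix.
#' @export
lightness_mask <- function(lab, cfg = seg_config()) {
  stopifnot(inherits(lab, "lab_image"))
  lab$L > cfg$lightness_threshold
}

#' Segment a trichrome image and measure percent collagen
#'
#' Full measurement chain: sRGB to L*a*b*, k = 2 clustering of the (a*, b*)
#' chroma, red/blue cluster identification, white override where L* exceeds
#' the uniform lightness threshold, morphological closing of the red and
#' blue regions, then
#' \deqn{\%\,collagen = 100 \cdot blue\_px / total\_px}
#' with `total_px = H * W`, the area of the entire image (white included) —
#' the literal area rule. `denominator = "tissue"` divides by
#' `total_px - white_px` instead.
#'
#' @param img `H x W x 3` 8-bit sRGB array, or a synthetic section from
#'   [generate_image()].
#' @param cfg A [seg_config()].
#' @return A `collagen_measurement`: list with the `class_mask` (integer
#'   matrix; 1 = red, 2 = blue, 3 = white), pixel counts `blue_px`,
#'   `red_px`, `white_px`, `total_px`, `percent_collagen`, a `degenerate`
#'   flag propagated from the clustering, and the `config` used.
#' @export
segment_image <- function(img, cfg = seg_config()) {
  if (inherits(img, "synthetic_section")) img <- img$image
  lab <- rgb_to_lab(img)
  white <- lightness_mask(lab, cfg)
  if (cfg$mask_before_cluster && any(!white)) {
    sub <- list(L = matrix(lab$L[!white], ncol = 1),
                a = matrix(lab$a[!white], ncol = 1),
                b = matrix(lab$b[!white], ncol = 1))
    class(sub) <- "lab_image"
    model <- label_clusters(cluster_ab(sub, cfg))
    cls <- matrix(MASK_RED, nrow(lab$L), ncol(lab$L))
    cls[!white] <- ifelse(model$class_map[model$assignment] == "blue",
                          MASK_BLUE, MASK_RED)
  } else {
    model <- label_clusters(cluster_ab(lab, cfg))
    cls <- matrix(ifelse(model$class_map[model$assignment] == "blue",
                         MASK_BLUE, MASK_RED),
                  nrow(lab$L), ncol(lab$L))
  }
  cls[white] <- MASK_WHITE
  cls <- close_regions(cls, cfg$closing_radius_px)
  blue <- sum(cls == MASK_BLUE)
  red <- sum(cls == MASK_RED)
  wht <- sum(cls == MASK_WHITE)
  total <- length(cls)
  denom <- if (cfg$denominator == "tissue") total - wht else total
  structure(list(class_mask = cls,
                 blue_px = blue, red_px = red, white_px = wht,
                 total_px = total,
                 percent_collagen = if (denom > 0) 100 * blue / denom else NA_real_,
                 degenerate = model$degenerate,
                 centroids = model$centroids,
                 config = cfg),
            class = "collagen_measurement")
}

#' @export
print.collagen_measurement <- function(x, ...) {
  cat(sprintf("<collagen_measurement> %.2f%% collagen (blue %d / red %d / white %d of %d px)%s\n",
              x$percent_collagen, x$blue_px, x$red_px, x$white_px, x$total_px,
              if (x$degenerate) " [degenerate clustering]" else ""))
  invisible(x)
}

#' Render a QC overlay of the classification
#'
#' Blends translucent class colours (red, blue, white) over the original
#' micrograph so automatic thresholds can be checked by eye, and attaches a
#' legend of per-class pixel counts.
#'
#' @param img `H x W x 3` 8-bit sRGB array.
#' @param mask Integer class mask (1 = red, 2 = blue, 3 = white), e.g.
#'   `segment_image(img, cfg)$class_mask`.
#' @param alpha Blend weight of the class colour (default 0.45).
#' @return `H x W x 3` 8-bit array with a `legend` attribute
#'   (data.frame: class, colour, pixels).
#' @export
render_overlay <- function(img, mask, alpha = 0.45) {
  if (inherits(img, "synthetic_section")) img <- img$image
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("expected an H x W x 3 image array")
  if (!all(dim(img)[1:2] == dim(mask)))
    stop("image and mask dimensions differ")
  pal <- rbind(red = c(255, 40, 40), blue = c(40, 40, 255),
               white = c(255, 255, 255))
  out <- img[, , 1:3, drop = FALSE] * 1.0
  for (k in 1:3) {
    sel <- mask == k
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * pal[k, ch]
      out[, , ch] <- plane
    }
  }
  out <- round(out)
  attr(out, "legend") <- data.frame(
    class = c("red", "blue", "white"),
    colour = c("#FF2828", "#2828FF", "#FFFFFF"),
    pixels = c(sum(mask == MASK_RED), sum(mask == MASK_BLUE),
               sum(mask == MASK_WHITE)))
  out
}
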