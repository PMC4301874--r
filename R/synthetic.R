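# Synthetic trichrome-stained muscle cross-sections with exact ground truth.
#
# Geometry: jittered-grid fiber seeds -> Voronoi tessellation (computed as
# half-plane intersections, so every cell is convex) clipped to a central
# tissue rectangle -> each cell shrunk inward by an endomysial collagen band
# whose width is solved by bisection to hit the target collagen area
# fraction. The raster and the polygons derive from the same half-planes,
# so label masks, fiber polygons and nucleus placements are mutually
# consistent. One nucleus per fiber, central or peripheral per cnf_rate,
# verified against the exact centrality predicate used by the CNF module.
#
# Coordinates: pixel centers at integer coordinates, origin top-left,
# x rightward (columns), y downward (rows); pixel (row r, col c) has center
# (x, y) = (c - 1, r - 1).

# ground-truth label codes
GT_BACKGROUND <- 0L
GT_MUSCLE <- 1L
GT_COLLAGEN <- 2L
GT_NUCLEUS <- 3L

#' Default trichrome stain colour model
#'
#' Class-mean CIE L*a*b* colours approximating Masson's trichrome:
#' red muscle cytoplasm, blue collagen, dark nuclei, white background.
#' Clear red/blue separation lives in the (a*, b*) plane.
#' @return Named list of length-3 (L*, a*, b*) vectors for classes
#'   `muscle`, `collagen`, `nucleus`, `background`.
#' @export
default_stain_model <- function() {
  list(muscle = c(L = 55, a = 45, b = 15),
       collagen = c(L = 60, a = 10, b = -35),
       nucleus = c(L = 25, a = 15, b = -20),
       background = c(L = 97, a = 0, b = 0))
}

#' Specification of a synthetic trichrome section
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param n_fibers Number of myofiber seeds.
#' @param target_collagen_fraction Desired collagen area fraction of the
#'   whole frame, in \[0, 1\].
#' @param background_fraction White background area fraction target, in
#'   \[0, 1); the tissue occupies the remaining central rectangle.
#' @param cnf_rate Probability that a fiber's nucleus is placed centrally.
#' @param stain_model Class-mean Lab colours (see [default_stain_model()]).
#' @param colour_noise_sd Per-channel Gaussian noise SD added in Lab space
#'   before conversion to sRGB (default 5).
#' @param nucleus_radius_px Painted nucleus disk radius (default 4).
#' @param band_frac Centrality band fraction shared with the CNF predicate
#'   (default 0.25): a nucleus is central iff its distance to the fiber
#'   boundary exceeds `band_frac * sqrt(area / pi)`.
#' @param seed RNG seed; identical spec (seed included) gives bit-identical
#'   output.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(width_px = 1024L, height_px = 1024L,
                           n_fibers = 200L,
                           target_collagen_fraction = 0.10,
                           background_fraction = 0.10,
                           cnf_rate = 0,
                           stain_model = default_stain_model(),
                           colour_noise_sd = 5,
                           nucleus_radius_px = 4L,
                           band_frac = 0.25,
                           seed = 1L) {
  stopifnot(width_px >= 32, height_px >= 32, n_fibers >= 1,
            target_collagen_fraction >= 0, target_collagen_fraction <= 1,
            background_fraction >= 0, background_fraction < 1,
            cnf_rate >= 0, cnf_rate <= 1, colour_noise_sd >= 0,
            band_frac > 0, band_frac < 1)
  if (target_collagen_fraction + background_fraction >= 1)
    stop("target_collagen_fraction + background_fraction must be < 1")
  cls <- c("muscle", "collagen", "nucleus", "background")
  if (!all(cls %in% names(stain_model)) ||
      !all(vapply(stain_model[cls], function(v) all(is.finite(v)) &&
                    length(v) == 3L, logical(1))))
    stop("stain_model must give finite (L*, a*, b*) means for ",
         paste(cls, collapse = ", "))
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_fibers = as.integer(n_fibers),
                 target_collagen_fraction = target_collagen_fraction,
                 background_fraction = background_fraction,
                 cnf_rate = cnf_rate, stain_model = stain_model[cls],
                 colour_noise_sd = colour_noise_sd,
                 nucleus_radius_px = as.integer(nucleus_radius_px),
                 band_frac = band_frac, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Sutherland-Hodgman clip of a convex polygon by half-plane n . x <= c
.clip_halfplane <- function(poly, nvec, cval) {
  k <- nrow(poly)
  if (k == 0L) return(poly)
  s <- poly %*% nvec - cval          # signed violation
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    pin <- s[i] <= 0; qin <- s[j] <= 0
    if (pin) out <- rbind(out, poly[i, ])
    if (xor(pin, qin)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

.polygon_area <- function(poly) {
  k <- nrow(poly)
  if (k < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:k, 1)] - x[c(2:k, 1)] * y)) / 2
}

# distance from a point to a polygon boundary (min over edge segments)
.point_boundary_dist <- function(pt, poly) {
  k <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:k, 1), 1]; y2 <- poly[c(2:k, 1), 2]
  ex <- x2 - x1; ey <- y2 - y1
  len2 <- ex^2 + ey^2
  t <- pmin(pmax(((pt[1] - x1) * ex + (pt[2] - y1) * ey) /
                   ifelse(len2 > 0, len2, 1), 0), 1)
  px <- x1 + t * ex; py <- y1 + t * ey
  sqrt(min((pt[1] - px)^2 + (pt[2] - py)^2))
}

#' Generate one synthetic trichrome section with ground truth
#'
#' See the package vignette for the geometric construction. The achieved
#' collagen fraction is guaranteed within 0.005 of the target, otherwise an
#' error names the achievable range.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_section`: list with `image` (`H x W x 3` 8-bit sRGB
#'   array), `gt` (ground truth: `label_mask` with codes 0 = background,
#'   1 = muscle, 2 = collagen, 3 = nucleus; `fiber_polygons` — named list of
#'   two-column vertex matrices; `nuclei` — data.frame x, y, fiber_id,
#'   is_central; `true_collagen_fraction`), the band width used, and the
#'   spec itself.
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  W <- spec$width_px; H <- spec$height_px; n <- spec$n_fibers
  .with_seed(spec$seed, {
    # tissue rectangle (continuous coords; pixel centers at 0..W-1, 0..H-1)
    sc <- sqrt(1 - spec$background_fraction)
    wt <- W * sc; ht <- H * sc
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    x0 <- cx - wt / 2; x1 <- cx + wt / 2
    y0 <- cy - ht / 2; y1 <- cy + ht / 2
    c0 <- max(1L, ceiling(x0 + 1)); c1 <- min(W, floor(x1 + 1))
    r0 <- max(1L, ceiling(y0 + 1)); r1 <- min(H, floor(y1 + 1))
    xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
    Wt <- length(xs); Ht <- length(ys)

    # jittered-grid seeds inside the tissue rectangle
    nx <- max(1L, round(sqrt(n * wt / ht)))
    ny <- ceiling(n / nx)
    cells <- sort(sample.int(nx * ny, n))
    ci <- (cells - 1L) %% nx; ri <- (cells - 1L) %/% nx
    cw <- wt / nx; ch <- ht / ny
    sx <- x0 + (ci + 0.1 + 0.8 * runif(n)) * cw
    sy <- y0 + (ri + 0.1 + 0.8 * runif(n)) * ch

    # nearest-seed assignment over the tissue subgrid
    best <- matrix(Inf, Ht, Wt)
    owner <- matrix(0L, Ht, Wt)
    for (j in seq_len(n)) {
      d2 <- outer((ys - sy[j])^2, (xs - sx[j])^2, "+")
      upd <- d2 < best
      best[upd] <- d2[upd]
      owner[upd] <- j
    }

    # neighbour sets within 5 grid spacings (margins beyond that exceed any
    # feasible band width)
    spacing <- sqrt(wt * ht / n)
    dseed <- as.matrix(stats::dist(cbind(sx, sy)))
    nbrs <- lapply(seq_len(n), function(i) {
      v <- which(dseed[i, ] <= 5 * spacing & seq_len(n) != i)
      if (length(v) < 3L && n > 1L)
        v <- order(dseed[i, ])[2:min(n, 8L)]
      v
    })

    # margin field: distance to the nearest Voronoi bisector or tissue edge
    xg <- rep(xs, each = Ht); yg <- rep(ys, times = Wt)
    owner_idx <- split(seq_along(owner), as.vector(owner))
    margin <- matrix(Inf, Ht, Wt)
    for (i in seq_len(n)) {
      idx <- owner_idx[[as.character(i)]]
      if (is.null(idx)) next
      px <- xg[idx]; py <- yg[idx]; di2 <- best[idx]
      m <- rep(Inf, length(idx))
      for (j in nbrs[[i]]) {
        dj2 <- (px - sx[j])^2 + (py - sy[j])^2
        m <- pmin(m, (dj2 - di2) / (2 * dseed[i, j]))
      }
      margin[idx] <- m
    }
    rect_d <- pmin(outer(pmin(ys - y0, y1 - ys), rep(1, Wt)),
                   outer(rep(1, Ht), pmin(xs - x0, x1 - xs)))
    margin <- pmin(margin, rect_d)

    # bisection on band width to hit the target collagen pixel count
    total <- as.numeric(W) * H
    C_target <- round(spec$target_collagen_fraction * total)
    n_tissue <- length(margin)
    if (C_target > n_tissue)
      stop(sprintf(paste0("infeasible collagen fraction %.3f: achievable ",
                          "range is [0, %.3f] at this background fraction"),
                   spec$target_collagen_fraction, n_tissue / total))
    # deterministic sub-pixel jitter (<= 1e-4 px) breaks exact ties in the
    # margin field (e.g. whole tissue-edge rows sharing one rect distance),
    # which would otherwise quantize the achievable collagen count
    mv <- as.vector(margin) +
      1e-4 * ((seq_along(margin) * 2654435761) %% 65536) / 65536
    lo <- 0; hi <- max(mv) + 1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (sum(mv < mid) < C_target) lo <- mid else hi <- mid
    }
    wband <- if (abs(sum(mv < lo) - C_target) <= abs(sum(mv < hi) - C_target))
      lo else hi
    achieved <- sum(mv < wband) / total
    if (abs(achieved - spec$target_collagen_fraction) > 0.005)
      stop(sprintf(paste0("band-width solver cannot reach fraction %.3f ",
                          "(closest achievable %.4f) with %d fibers; ",
                          "achievable range is [0, %.3f]"),
                   spec$target_collagen_fraction, achieved, n,
                   n_tissue / total))

    # label mask (thresholding the jittered margin, matching the solver)
    label <- matrix(GT_BACKGROUND, H, W)
    sub <- matrix(GT_COLLAGEN, Ht, Wt)
    sub[matrix(mv, Ht, Wt) >= wband] <- GT_MUSCLE
    label[r0:r1, c0:c1] <- sub

    # fiber polygons: tissue rectangle inset by the band, clipped by each
    # neighbour's bisector half-plane offset inward by the band width
    inset <- rbind(c(x0 + wband, y0 + wband), c(x1 - wband, y0 + wband),
                   c(x1 - wband, y1 - wband), c(x0 + wband, y1 - wband))
    polys <- vector("list", n)
    for (i in seq_len(n)) {
      poly <- inset
      for (j in nbrs[[i]]) {
        u <- c(sx[j] - sx[i], sy[j] - sy[i]) / dseed[i, j]
        cval <- sum(u * c(sx[i] + sx[j], sy[i] + sy[j]) / 2) - wband
        poly <- .clip_halfplane(poly, u, cval)
        if (nrow(poly) < 3L) break
      }
      polys[[i]] <- poly
    }

    # one nucleus per retained fiber; placement verified against the exact
    # centrality predicate so cnf_rate 0/1 agree with it without exception
    central_draw <- stats::runif(n) < spec$cnf_rate
    keep <- logical(n)
    nuc <- vector("list", n)
    band_frac <- spec$band_frac
    for (i in seq_len(n)) {
      poly <- polys[[i]]
      if (is.null(poly) || nrow(poly) < 3L) next
      area <- .polygon_area(poly)
      if (area < 60) next                       # too small to host a nucleus
      r_eq <- sqrt(area / pi)
      idx <- owner_idx[[as.character(i)]]
      idx <- idx[margin[idx] >= wband]
      if (!length(idx)) next
      bd <- margin[idx] - wband
      thr <- band_frac * r_eq
      if (central_draw[i]) {
        ord <- idx[order(bd, decreasing = TRUE)]
        cand <- utils::head(ord, 50L)
      } else {
        ok <- which(bd >= 0.75 & bd <= max(thr - 0.75, 1))
        if (!length(ok)) next
        cand <- idx[ok[order(abs(bd[ok] - 0.5 * thr))]]
        cand <- utils::head(cand, 50L)
      }
      placed <- FALSE
      for (ix in cand) {
        pt <- c(xg[ix], yg[ix])
        d <- .point_boundary_dist(pt, poly)
        good <- if (central_draw[i]) d > thr + 0.5 else (d > 0 && d < thr - 0.25)
        if (good) {
          nuc[[i]] <- data.frame(x = pt[1], y = pt[2], fiber_id = i,
                                 is_central = central_draw[i])
          keep[i] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) keep[i] <- FALSE
    }
    nuclei <- do.call(rbind, nuc[keep])
    if (is.null(nuclei))
      nuclei <- data.frame(x = numeric(0), y = numeric(0),
                           fiber_id = integer(0), is_central = logical(0))
    rownames(nuclei) <- NULL

    # paint nucleus disks over muscle pixels of their own fiber
    nr <- spec$nucleus_radius_px
    for (i in which(keep)) {
      pt <- c(nuc[[i]]$x, nuc[[i]]$y)
      rr <- max(r0, floor(pt[2] - nr) + 1L):min(r1, ceiling(pt[2] + nr) + 1L)
      cc <- max(c0, floor(pt[1] - nr) + 1L):min(c1, ceiling(pt[1] + nr) + 1L)
      for (r in rr) for (cl in cc) {
        if (label[r, cl] == GT_MUSCLE &&
            (cl - 1 - pt[1])^2 + (r - 1 - pt[2])^2 <= nr^2 &&
            owner[r - r0 + 1L, cl - c0 + 1L] == i)
          label[r, cl] <- GT_NUCLEUS
      }
    }

    fiber_polygons <- polys[keep]
    names(fiber_polygons) <- as.character(which(keep))

    # render: class-mean Lab + Gaussian noise -> sRGB, clipped, 8-bit
    sm <- spec$stain_model
    means <- rbind(sm$background, sm$muscle, sm$collagen, sm$nucleus)
    lv <- as.vector(label) + 1L
    labpix <- means[lv, , drop = FALSE]
    if (spec$colour_noise_sd > 0) {
      npx <- length(lv)
      labpix <- labpix + cbind(stats::rnorm(npx, 0, spec$colour_noise_sd),
                               stats::rnorm(npx, 0, spec$colour_noise_sd),
                               stats::rnorm(npx, 0, spec$colour_noise_sd))
    }
    rgb <- round(lab_to_srgb_mat(labpix) * 255)
    image <- array(0L, dim = c(H, W, 3))
    image[, , 1] <- as.integer(rgb[, 1])
    image[, , 2] <- as.integer(rgb[, 2])
    image[, , 3] <- as.integer(rgb[, 3])

    structure(list(
      image = image,
      gt = list(label_mask = label,
                fiber_polygons = fiber_polygons,
                nuclei = nuclei,
                true_collagen_fraction = sum(label == GT_COLLAGEN) / total),
      band_width = wband,
      spec = spec), class = "synthetic_section")
  })
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_section %d x %d> collagen %.4f (target %.4f), ",
                     "%d fibers, %d nuclei (%d central)\n"),
              x$spec$height_px, x$spec$width_px,
              x$gt$true_collagen_fraction, x$spec$target_collagen_fraction,
              length(x$gt$fiber_polygons), nrow(x$gt$nuclei),
              sum(x$gt$nuclei$is_central)))
  invisible(x)
}

#' Generate a cohort of synthetic sections mirroring a study design
#'
#' Groups of animals with several sections per animal, mimicking a design
#' where five sections are imaged per tissue. Per-image seeds are derived
#' deterministically from (base seed, group, animal, section).
#'
#' @param groups A data.frame with columns `group`, `n_animals`,
#'   `sections_per_animal`, `target_collagen_fraction`, `cnf_rate`.
#' @param base_seed Integer base seed.
#' @param width_px,height_px,n_fibers,... Passed to [synthetic_spec()] for
#'   every image.
#' @param out_dir If non-`NULL`, images / ground truth / annotations are
#'   written there (PNG + GeoJSON) and the manifest records the paths;
#'   otherwise sections are kept in memory in `$sections`.
#' @return List with `manifest` (data.frame: group, animal, section,
#'   image_path, gt_path, annotation_path, true_fraction, cnf_rate, seed)
#'   and `sections` (list, parallel to manifest rows; `NULL`s when written
#'   to disk).
#' @export
generate_cohort <- function(groups, base_seed = 1L, width_px = 512L,
                            height_px = 512L, n_fibers = 100L,
                            out_dir = NULL, ...) {
  need <- c("group", "n_animals", "sections_per_animal",
            "target_collagen_fraction", "cnf_rate")
  stopifnot(is.data.frame(groups), all(need %in% names(groups)))
  if (anyDuplicated(groups$group))
    stop("duplicate group labels in cohort specification")
  rows <- list(); sections <- list(); k <- 0L
  for (g in seq_len(nrow(groups))) {
    for (a in seq_len(groups$n_animals[g])) {
      for (s in seq_len(groups$sections_per_animal[g])) {
        k <- k + 1L
        seed_img <- as.integer((as.numeric(base_seed) * 7919 +
                                  g * 104729 + a * 1009 + s * 101) %% 2147483629)
        spec <- synthetic_spec(
          width_px = width_px, height_px = height_px, n_fibers = n_fibers,
          target_collagen_fraction = groups$target_collagen_fraction[g],
          cnf_rate = groups$cnf_rate[g], seed = seed_img, ...)
        sec <- generate_image(spec)
        ip <- gp <- ap <- NA_character_
        if (!is.null(out_dir)) {
          tag <- sprintf("%s_a%02d_s%02d", groups$group[g], a, s)
          ip <- file.path(out_dir, paste0(tag, ".png"))
          gp <- file.path(out_dir, paste0(tag, "_gt.png"))
          ap <- file.path(out_dir, paste0(tag, ".geojson"))
          write_section(sec, ip, gp, ap)
        }
        rows[[k]] <- data.frame(
          group = groups$group[g], animal = a, section = s,
          image_path = ip, gt_path = gp, annotation_path = ap,
          true_fraction = sec$gt$true_collagen_fraction,
          cnf_rate = groups$cnf_rate[g], seed = seed_img,
          stringsAsFactors = FALSE)
        sections[[k]] <- if (is.null(out_dir)) sec else NULL
      }
    }
  }
  manifest <- do.call(rbind, rows)
  key <- with(manifest, paste(group, animal, section))
  if (anyDuplicated(key)) stop("duplicate (group, animal, section) keys")
  list(manifest = manifest, sections = sections)
}
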