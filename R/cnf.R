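# Centrally nucleated fiber (CNF) analysis from fiber / nucleus annotations.
#
# The regeneration metric: percent of myofibers with at least one centrally
# located nucleus. Centrality is operationalized as distance from the
# nucleus to the fiber boundary exceeding band_frac * equivalent radius,
# with equivalent radius sqrt(area / pi); band_frac defaults to 0.25.

#' Create a fiber annotation
#'
#' @param fiber_id Identifier.
#' @param polygon Two-column matrix of vertex coordinates (closed ring; a
#'   repeated last vertex is tolerated and dropped). Must be simple with
#'   positive area.
#' @return A `fiber_annotation` list.
#' @export
fiber_annotation <- function(fiber_id, polygon) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2, all(is.finite(polygon)))
  k <- nrow(polygon)
  if (k >= 2 && all(polygon[1, ] == polygon[k, ]))
    polygon <- polygon[-k, , drop = FALSE]
  if (nrow(polygon) < 3) stop("fiber polygon needs at least 3 vertices")
  if (.polygon_area(polygon) <= 0) stop("fiber polygon must have area > 0")
  if (.polygon_self_intersects(polygon))
    stop("fiber polygon must be simple (non-self-intersecting)")
  structure(list(fiber_id = fiber_id, polygon = polygon),
            class = "fiber_annotation")
}

# O(k^2) segment-intersection check; annotation polygons are small
.polygon_self_intersects <- function(poly) {
  k <- nrow(poly)
  seg <- cbind(poly, poly[c(2:k, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(k - 2)) {
    for (j in (i + 2):k) {
      if (i == 1 && j == k) next          # adjacent through the wrap
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Assign nuclei to the fibers containing them
#'
#' Point-in-polygon with boundary counting as inside. Nuclei contained in no
#' fiber stay unassigned (`fiber_id` `NA`) and are excluded from the CNF
#' tally; a point inside more than one fiber polygon is an error (the
#' annotation set overlaps).
#'
#' @param fibers List of [fiber_annotation()]s.
#' @param nuclei data.frame with columns `x`, `y` (and optionally
#'   `fiber_id`, which is overwritten).
#' @return The nuclei data.frame with `fiber_id` filled (NA = unassigned).
#' @export
assign_nuclei <- function(fibers, nuclei) {
  stopifnot(is.data.frame(nuclei), all(c("x", "y") %in% names(nuclei)),
            all(is.finite(nuclei$x)), all(is.finite(nuclei$y)))
  ids <- vapply(fibers, function(f) as.character(f$fiber_id), character(1))
  hit <- matrix(FALSE, nrow(nuclei), length(fibers))
  for (j in seq_along(fibers)) {
    p <- fibers[[j]]$polygon
    hit[, j] <- sp::point.in.polygon(nuclei$x, nuclei$y, p[, 1], p[, 2]) > 0
  }
  nh <- rowSums(hit)
  if (any(nh > 1)) {
    bad <- which(nh > 1)[1]
    stop("nucleus at (", nuclei$x[bad], ", ", nuclei$y[bad],
         ") lies inside overlapping fibers: ",
         paste(ids[hit[bad, ]], collapse = ", "))
  }
  nuclei$fiber_id <- ifelse(nh == 1, ids[apply(hit, 1, function(r)
    if (any(r)) which(r) else NA_integer_)], NA_character_)
  nuclei
}

#' Centrality predicate for one nucleus
#'
#' A nucleus is central iff its distance to the fiber boundary exceeds
#' `band_frac * sqrt(area / pi)`. A point exactly on the boundary has
#' distance 0 and is therefore peripheral.
#'
#' @param point Numeric length-2 (x, y).
#' @param fiber A [fiber_annotation()].
#' @param band_frac Peripheral band fraction of the equivalent radius,
#'   in (0, 1); default 0.25.
#' @return Logical flag.
#' @export
is_central <- function(point, fiber, band_frac = 0.25) {
  stopifnot(band_frac > 0, band_frac < 1)
  poly <- fiber$polygon
  r_eq <- sqrt(.polygon_area(poly) / pi)
  .point_boundary_dist(point, poly) > band_frac * r_eq
}

#' Percent of centrally nucleated fibers
#'
#' A fiber counts as centrally nucleated if at least one of its assigned
#' nuclei is central; the percentage is over all annotated fibers.
#'
#' @param fibers List of [fiber_annotation()]s (at least one).
#' @param nuclei data.frame with `x`, `y` and optionally `fiber_id`; if
#'   `fiber_id` is absent it is computed with [assign_nuclei()].
#' @param band_frac See [is_central()].
#' @return A `cnf_result`: list with `n_fibers`, `n_central_fibers`,
#'   `percent_cnf`, `band_frac`.
#' @export
percent_cnf <- function(fibers, nuclei, band_frac = 0.25) {
  if (length(fibers) == 0)
    stop("percent CNF is undefined for zero fibers")
  if (!"fiber_id" %in% names(nuclei) || anyNA(nuclei$fiber_id))
    nuclei <- assign_nuclei(fibers, nuclei)
  ids <- vapply(fibers, function(f) as.character(f$fiber_id), character(1))
  central_ids <- character(0)
  for (j in seq_along(fibers)) {
    sel <- which(!is.na(nuclei$fiber_id) & nuclei$fiber_id == ids[j])
    if (any(vapply(sel, function(i)
      is_central(c(nuclei$x[i], nuclei$y[i]), fibers[[j]], band_frac),
      logical(1))))
      central_ids <- c(central_ids, ids[j])
  }
  n <- length(fibers); nc <- length(central_ids)
  structure(list(n_fibers = n, n_central_fibers = nc,
                 percent_cnf = 100 * nc / n, band_frac = band_frac,
                 central_fiber_ids = central_ids),
            class = "cnf_result")
}

#' @export
print.cnf_result <- function(x, ...) {
  cat(sprintf("<cnf_result> %.2f%% CNF (%d of %d fibers; band_frac %.2f)\n",
              x$percent_cnf, x$n_central_fibers, x$n_fibers, x$band_frac))
  invisible(x)
}

#' Extract fiber annotations from a synthetic section
#'
#' @param section A `synthetic_section` from [generate_image()].
#' @return List of [fiber_annotation()]s.
#' @export
gt_fibers <- function(section) {
  stopifnot(inherits(section, "synthetic_section"))
  mapply(fiber_annotation, names(section$gt$fiber_polygons),
         section$gt$fiber_polygons, SIMPLIFY = FALSE)
}
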