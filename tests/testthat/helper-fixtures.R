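# shared fixtures: all built in code at test time

# uniform-colour 8-bit image
solid_image <- function(rgb, h = 8, w = 8) {
  array(rep(as.numeric(rgb), each = h * w), dim = c(h, w, 3))
}

# image from a Lab colour (through the package's own inverse transform)
solid_lab_image <- function(lab, h = 8, w = 8) {
  rgb <- round(fibroquant:::lab_to_srgb_mat(matrix(lab, 1)) * 255)
  solid_image(rgb, h, w)
}

# small synthetic section, fast defaults for unit tests
small_spec <- function(...) {
  args <- list(width_px = 192L, height_px = 192L, n_fibers = 30L,
               target_collagen_fraction = 0.10, colour_noise_sd = 5,
               seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# square fiber annotation centred at (cx, cy) with half-side s
square_fiber <- function(id, cx, cy, s) {
  fiber_annotation(id, cbind(c(cx - s, cx + s, cx + s, cx - s),
                             c(cy - s, cy - s, cy + s, cy + s)))
}

# regular-polygon approximation of a circle fiber
circle_fiber <- function(id, cx, cy, r, k = 64) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  fiber_annotation(id, cbind(cx + r * cos(th), cy + r * sin(th)))
}

# brute-force morphology oracle: max/min filter over the disk neighbourhood
brute_dilate <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  off <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
  off <- off[off[, 1]^2 + off[, 2]^2 <= r^2, , drop = FALSE]
  for (i in 1:h) for (j in 1:w) {
    ys <- i + off[, 1]; xs <- j + off[, 2]
    sel <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    out[i, j] <- any(mask[cbind(ys[sel], xs[sel])])
  }
  out
}
brute_close <- function(mask, r) {
  d <- brute_dilate(mask, r)
  !brute_dilate(!d, r)   # erosion as complement-dual
}

# random group data for statistics oracles
random_groups <- function(k = 4, nmin = 3, nmax = 8) {
  setNames(lapply(seq_len(k), function(i)
    rnorm(sample(nmin:nmax, 1), mean = runif(1, 0, 10),
          sd = runif(1, 0.5, 3))), paste0("g", seq_len(k)))
}
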