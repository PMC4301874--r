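test_that("centrality: circle fiber, centre is central, boundary is peripheral", {
  f <- circle_fiber("c", 0, 0, 50)
  expect_true(is_central(c(0, 0), f))              # 50 > 0.25 * ~50
  expect_false(is_central(c(50, 0), f))            # on the boundary, distance 0
  expect_false(is_central(c(45, 0), f))            # within the peripheral band
})

test_that("annotation validation rejects bad polygons", {
  expect_error(fiber_annotation("x", cbind(c(0, 1), c(0, 1))), "3 vertices")
  expect_error(fiber_annotation("x", cbind(c(0, 1, 2), c(0, 0, 0))), "area")
  bow <- cbind(c(0, 6, 1, 5), c(0, 0, 3, 3))       # self-intersecting bow-tie
  expect_error(fiber_annotation("x", bow), "simple")
})

test_that("nuclei are assigned by containment, boundary inclusive", {
  f1 <- square_fiber("a", 10, 10, 5)
  f2 <- square_fiber("b", 30, 10, 5)
  nuc <- data.frame(x = c(10, 30, 60, 15), y = c(10, 10, 10, 10))
  out <- assign_nuclei(list(f1, f2), nuc)
  expect_identical(out$fiber_id, c("a", "b", NA, "a"))  # x=15: on a's edge
  # overlapping fibers sharing a point -> error naming both
  f3 <- square_fiber("c", 12, 10, 5)
  expect_error(assign_nuclei(list(f1, f3),
                             data.frame(x = 11, y = 10)), "a, c")
})

test_that("percent CNF arithmetic and edge cases", {
  fibers <- lapply(1:4, function(i) square_fiber(i, 20 * i, 0, 5))
  nuc <- data.frame(x = c(20, 40, 60, 62), y = c(0, 0, 0, 4.2))
  r <- percent_cnf(fibers, nuc)       # nuclei 1-3 central, 4 peripheral
  expect_identical(r$n_fibers, 4L)
  expect_identical(r$n_central_fibers, 3L)
  expect_equal(r$percent_cnf, 75)
  expect_error(percent_cnf(list(), nuc), "zero fibers")
  none <- percent_cnf(fibers, data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(none$percent_cnf, 0)
})

test_that("percent CNF is invariant under rigid motions", {
  set.seed(14)
  fibers <- lapply(1:6, function(i) circle_fiber(i, 40 * i, 10 * i, 12))
  nuc <- data.frame(x = 40 * (1:6) + runif(6, -8, 8),
                    y = 10 * (1:6) + runif(6, -8, 8))
  base <- percent_cnf(fibers, nuc)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mv <- function(xy) sweep(xy %*% R, 2, c(-5, 12), "+")
  fibers2 <- lapply(fibers, function(f)
    fiber_annotation(f$fiber_id, mv(f$polygon)))
  xy2 <- mv(cbind(nuc$x, nuc$y))
  r2 <- percent_cnf(fibers2, data.frame(x = xy2[, 1], y = xy2[, 2]))
  expect_identical(r2$n_central_fibers, base$n_central_fibers)
  expect_equal(r2$percent_cnf, base$percent_cnf)
})

test_that("shrinking the band never loses central fibers", {
  sec <- generate_image(small_spec(width_px = 256L, height_px = 256L,
                                   n_fibers = 40L, cnf_rate = 0.5, seed = 19))
  fib <- gt_fibers(sec)
  nuc <- sec$gt$nuclei; nuc$fiber_id <- as.character(nuc$fiber_id)
  counts <- vapply(c(0.4, 0.3, 0.25, 0.15, 0.05),
                   function(bf) percent_cnf(fib, nuc, bf)$n_central_fibers,
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("synthetic ground truth is recovered exactly", {
  sec <- generate_image(small_spec(width_px = 256L, height_px = 256L,
                                   n_fibers = 40L, cnf_rate = 0.4, seed = 71))
  fib <- gt_fibers(sec)
  nuc <- sec$gt$nuclei[, c("x", "y")]    # strip ids: force re-assignment
  assigned <- assign_nuclei(fib, nuc)
  expect_identical(assigned$fiber_id, as.character(sec$gt$nuclei$fiber_id))
  r <- percent_cnf(fib, assigned)
  expect_equal(r$percent_cnf, 100 * mean(sec$gt$nuclei$is_central))
})

test_that("annotations survive a GeoJSON round trip with identical CNF result", {
  sec <- generate_image(small_spec(seed = 37, cnf_rate = 0.6))
  fib <- gt_fibers(sec)
  nuc <- sec$gt$nuclei; nuc$fiber_id <- as.character(nuc$fiber_id)
  before <- percent_cnf(fib, nuc)
  td <- withr::local_tempdir()
  p <- file.path(td, "ann.geojson")
  write_annotations(fib, nuc, p)
  ann <- read_annotations(p)
  after <- percent_cnf(ann$fibers, ann$nuclei)
  expect_identical(after$n_fibers, before$n_fibers)
  expect_identical(after$n_central_fibers, before$n_central_fibers)
  expect_equal(after$percent_cnf, before$percent_cnf)
})
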