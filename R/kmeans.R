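# k = 2 k-means on the (a*, b*) chroma plane.
#
# Hand-rolled Lloyd iterations with k-means++ seeding so that the result is
# exactly reproducible from `kmeans_seed` and honours the configured
# convergence tolerance; stats::kmeans is kept as a cross-check oracle in the
# test suite.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# one Lloyd run for k = 2 from given initial centroids; x is n x 2.
# Runs to the exact Lloyd fixed point (assignment unchanged) so the result
# is invariant under pixel-order permutation; the inertia tolerance is a
# secondary stop for pathologically slow convergence.
.lloyd2 <- function(x, cen, tol, max_iter = 100L) {
  n <- nrow(x)
  inertia <- Inf
  assign <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    # assign by the linear discriminant between the two centroids
    w <- cen[1, ] - cen[2, ]
    if (all(w == 0)) {
      assign_new <- rep(1L, n)
    } else {
      thr <- (sum(cen[1, ]^2) - sum(cen[2, ]^2)) / 2
      assign_new <- 2L - (drop(x %*% w) > thr)
    }
    stable <- identical(assign_new, assign)
    assign <- assign_new
    if (stable) break
    # recompute centroids; an emptied cluster grabs the farthest point
    for (k in 1:2) {
      if (!any(assign == k)) {
        d2 <- (x[, 1] - cen[3 - k, 1])^2 + (x[, 2] - cen[3 - k, 2])^2
        assign[which.max(d2)] <- k
      }
    }
    cen_new <- rbind(colMeans(x[assign == 1L, , drop = FALSE]),
                     colMeans(x[assign == 2L, , drop = FALSE]))
    d2 <- (x[, 1] - cen_new[assign, 1])^2 + (x[, 2] - cen_new[assign, 2])^2
    inertia_new <- sum(d2)
    cen <- cen_new
    if (is.finite(inertia) && inertia_new > 0 &&
        abs(inertia - inertia_new) <= tol * inertia)
      { inertia <- inertia_new; break }
    inertia <- inertia_new
  }
  list(centroids = cen, assignment = assign, inertia = inertia)
}

.kmeanspp_init <- function(x) {
  n <- nrow(x)
  i1 <- sample.int(n, 1L)
  d2 <- (x[, 1] - x[i1, 1])^2 + (x[, 2] - x[i1, 2])^2
  s <- sum(d2)
  i2 <- if (s <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = d2 / s)
  rbind(x[i1, ], x[i2, ])
}

#' Cluster image pixels into two chroma groups
#'
#' Runs k-means with k = 2 on the (a*, b*) values of every pixel, the step
#' that separates the red-stained muscle from the blue-stained collagen.
#' Best of `kmeans_restarts` k-means++ starts by within-cluster sum of
#' squares; Lloyd iterations stop when the relative inertia change drops
#' below `kmeans_tol`. Fully deterministic given `kmeans_seed`.
#'
#' If all pixels share one (a*, b*) value the model is flagged degenerate:
#' a single effective centroid classifies the whole image.
#'
#' @param lab A `lab_image` (see [rgb_to_lab()]).
#' @param cfg A [seg_config()] list.
#' @return A `cluster_model`: list with `centroids` (2 x 2 matrix, columns
#'   a*, b*), integer `assignment` per pixel (matrix), `inertia`,
#'   `degenerate` flag and (after [label_clusters()]) `class_map`.
#' @export
cluster_ab <- function(lab, cfg = seg_config()) {
  stopifnot(inherits(lab, "lab_image"))
  x <- cbind(as.vector(lab$a), as.vector(lab$b))
  if (nrow(x) < 2L) stop("image must contain at least 2 pixels")
  h <- nrow(lab$L); w <- ncol(lab$L)
  rng <- c(diff(range(x[, 1])), diff(range(x[, 2])))
  if (all(rng == 0)) {
    model <- list(centroids = rbind(x[1, ], x[1, ]),
                  assignment = matrix(1L, h, w),
                  inertia = 0, degenerate = TRUE, class_map = NULL)
    class(model) <- "cluster_model"
    return(model)
  }
  best <- NULL
  .with_seed(cfg$kmeans_seed, {
    for (r in seq_len(cfg$kmeans_restarts)) {
      fit <- .lloyd2(x, .kmeanspp_init(x), cfg$kmeans_tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  model <- list(centroids = best$centroids,
                assignment = matrix(best$assignment, h, w),
                inertia = best$inertia, degenerate = FALSE, class_map = NULL)
  class(model) <- "cluster_model"
  model
}

#' Identify the red and the blue cluster
#'
#' The centroid with the smaller b* (more blue on the blue--yellow axis) is
#' the collagen ("blue") cluster; the other is muscle ("red"). An exact tie
#' on b* is broken by a*: the centroid with the larger a* is red.
#'
#' @param model A `cluster_model` from [cluster_ab()].
#' @return The model with `class_map` filled: a named character vector
#'   mapping cluster index `"1"`/`"2"` to `"red"`/`"blue"`.
#' @export
label_clusters <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  cen <- model$centroids
  if (model$degenerate) {
    cls <- if (cen[1, 2] < 0) "blue" else "red"
    model$class_map <- c("1" = cls, "2" = cls)
    return(model)
  }
  blue_idx <- if (cen[1, 2] < cen[2, 2]) 1L
              else if (cen[1, 2] > cen[2, 2]) 2L
              else if (cen[1, 1] > cen[2, 1]) 2L else 1L  # tie: larger a* red
  cm <- c("red", "red"); cm[blue_idx] <- "blue"
  names(cm) <- c("1", "2")
  model$class_map <- cm
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model>\n")
  cen <- round(x$centroids, 2)
  for (k in 1:2)
    cat(sprintf("  centroid %d: a*=%.2f b*=%.2f%s\n", k, cen[k, 1], cen[k, 2],
                if (!is.null(x$class_map)) paste0(" -> ", x$class_map[k]) else ""))
  if (x$degenerate) cat("  (degenerate: single effective cluster)\n")
  invisible(x)
}
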