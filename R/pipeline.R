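# Study orchestration: cohort manifest -> per-image segmentation (+ CNF
# when annotations are present) -> per-animal aggregation -> group
# statistics -> report.
#
# Unit of replication is the animal: fields/sections are averaged with
# unweighted means at each level before any statistics.

#' Quantify every image of a cohort
#'
#' Runs [segment_image()] on each manifest row (and [percent_cnf()] when an
#' annotation path or in-memory ground truth is present). Row failures are
#' recorded, not fatal: the run continues and the failing row carries the
#' error message in `status`.
#'
#' @param cohort Either a list with `manifest` and `sections` (as returned
#'   by [generate_cohort()]) or a manifest data.frame whose `image_path`
#'   (and optional `annotation_path`) columns point at files on disk.
#' @param cfg A [seg_config()].
#' @param out_dir If non-`NULL`, QC overlays are written there as PNG.
#' @param band_frac Centrality band for the CNF metric (default 0.25).
#' @return Per-image data.frame: manifest keys plus `blue_px`, `red_px`,
#'   `white_px`, `total_px`, `percent_collagen`, `percent_cnf` (NA without
#'   annotations), `degenerate`, `status` ("ok" or the error message).
#' @export
run_quantify <- function(cohort, cfg = seg_config(), out_dir = NULL,
                         band_frac = 0.25) {
  if (is.data.frame(cohort)) cohort <- list(manifest = cohort, sections = NULL)
  manifest <- cohort$manifest
  stopifnot(is.data.frame(manifest),
            all(c("group", "animal", "section") %in% names(manifest)))
  if (!"muscle" %in% names(manifest)) manifest$muscle <- "muscle"
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    base <- data.frame(group = manifest$group[i], animal = manifest$animal[i],
                       muscle = manifest$muscle[i],
                       section = manifest$section[i],
                       stringsAsFactors = FALSE)
    rows[[i]] <- tryCatch({
      sec <- if (!is.null(cohort$sections) && !is.null(cohort$sections[[i]]))
        cohort$sections[[i]] else NULL
      img <- if (!is.null(sec)) sec$image else read_image(manifest$image_path[i])
      m <- segment_image(img, cfg)
      pc_cnf <- NA_real_
      fib <- nuc <- NULL
      if (!is.null(sec) && length(sec$gt$fiber_polygons)) {
        fib <- gt_fibers(sec); nuc <- sec$gt$nuclei
      } else if ("annotation_path" %in% names(manifest) &&
                 !is.na(manifest$annotation_path[i]) &&
                 nzchar(manifest$annotation_path[i])) {
        ann <- read_annotations(manifest$annotation_path[i])
        fib <- ann$fibers; nuc <- ann$nuclei
      }
      if (!is.null(fib) && length(fib))
        pc_cnf <- percent_cnf(fib, nuc, band_frac)$percent_cnf
      if (!is.null(out_dir)) {
        ov <- render_overlay(img, m$class_mask)
        write_image(ov, file.path(out_dir,
          sprintf("overlay_%s_a%02d_s%02d.png", base$group, base$animal,
                  base$section)))
      }
      cbind(base, data.frame(
        blue_px = m$blue_px, red_px = m$red_px, white_px = m$white_px,
        total_px = m$total_px, percent_collagen = m$percent_collagen,
        percent_cnf = pc_cnf, degenerate = m$degenerate, status = "ok",
        stringsAsFactors = FALSE))
    }, error = function(e) cbind(base, data.frame(
      blue_px = NA_integer_, red_px = NA_integer_, white_px = NA_integer_,
      total_px = NA_integer_, percent_collagen = NA_real_,
      percent_cnf = NA_real_, degenerate = NA,
      status = paste("failed:", conditionMessage(e)),
      stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}

#' Aggregate per-image results to per-animal values
#'
#' Unweighted mean over an animal's sections, per muscle and metric.
#' Animals with no successful rows are excluded with a warning.
#'
#' @param per_image Output of [run_quantify()].
#' @return Per-animal data.frame: `group`, `animal`, `muscle`,
#'   `percent_collagen_mean`, `percent_cnf_mean`, `n_sections`.
#' @export
aggregate_animals <- function(per_image) {
  ok <- per_image[per_image$status == "ok", , drop = FALSE]
  lost <- unique(per_image[per_image$status != "ok",
                           c("group", "animal", "muscle")])
  if (nrow(lost)) {
    have <- unique(ok[, c("group", "animal", "muscle")])
    gone <- !paste(lost$group, lost$animal, lost$muscle) %in%
      paste(have$group, have$animal, have$muscle)
    if (any(gone))
      warning("animals with zero successful sections excluded: ",
              paste(lost$group[gone], lost$animal[gone], sep = "/",
                    collapse = ", "))
  }
  if (!nrow(ok)) stop("no successful per-image rows to aggregate")
  key <- interaction(ok$group, ok$animal, ok$muscle, drop = TRUE)
  parts <- split(ok, key)
  out <- do.call(rbind, lapply(parts, function(d) data.frame(
    group = d$group[1], animal = d$animal[1], muscle = d$muscle[1],
    percent_collagen_mean = mean(d$percent_collagen),
    percent_cnf_mean = if (all(is.na(d$percent_cnf))) NA_real_
                       else mean(d$percent_cnf, na.rm = TRUE),
    n_sections = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$muscle, out$group, out$animal), , drop = FALSE]
}

#' Group statistics over a per-animal table
#'
#' For every muscle and metric with at least two groups of at least two
#' animals: group summaries, one-way ANOVA, Tukey-Kramer comparisons and
#' star codes. Metrics that cannot be tested are skipped with a warning.
#'
#' @param per_animal Output of [aggregate_animals()].
#' @param alpha Significance threshold (default 0.05).
#' @return A `study_report`: list with `per_animal`, and per muscle/metric
#'   a list of `summaries`, `anova`, `tukey`.
#' @export
run_stats <- function(per_animal, alpha = 0.05) {
  metrics <- c(percent_collagen = "percent_collagen_mean",
               percent_cnf = "percent_cnf_mean")
  results <- list()
  for (mus in unique(per_animal$muscle)) {
    dm <- per_animal[per_animal$muscle == mus, , drop = FALSE]
    for (mn in names(metrics)) {
      v <- dm[[metrics[[mn]]]]
      d <- dm[!is.na(v), , drop = FALSE]
      if (!nrow(d)) next
      sizes <- table(d$group)
      usable <- names(sizes)[sizes >= 2]
      if (length(usable) < 2) {
        warning(sprintf("metric %s / muscle %s skipped: fewer than 2 groups with n >= 2",
                        mn, mus))
        next
      }
      d <- d[d$group %in% usable, , drop = FALSE]
      vals <- split(d[[metrics[[mn]]]], as.character(d$group))
      summ <- do.call(rbind, mapply(summarize_group, vals, names(vals),
                                    SIMPLIFY = FALSE))
      tk <- tukey_hsd(summ, alpha = alpha)
      results[[paste(mus, mn, sep = ".")]] <-
        list(muscle = mus, metric = mn, summaries = summ,
             anova = attr(tk, "anova"), tukey = tk)
    }
  }
  structure(list(per_animal = per_animal, results = results, alpha = alpha,
                 version = as.character(utils::packageVersion("fibroquant"))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (r in x$results) {
    cat(sprintf("  %s / %s: F(%d, %d) = %.3f, p = %.4g %s\n",
                r$muscle, r$metric, r$anova$df_between, r$anova$df_within,
                r$anova$F, r$anova$p, stars(r$anova$p)))
  }
  invisible(x)
}

#' Serialize a study report to JSON (plus CSV tables)
#'
#' @param report A `study_report`.
#' @param path JSON destination; `<path>_per_animal.csv` is written
#'   alongside.
#' @export
write_report <- function(report, path) {
  out <- list(version = report$version, alpha = report$alpha,
              results = lapply(report$results, function(r) list(
                muscle = r$muscle, metric = r$metric,
                summaries = r$summaries,
                anova = r$anova[c("k_groups", "df_between", "df_within",
                                  "ss_between", "ss_within", "F", "p")],
                tukey = as.data.frame(r$tukey))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_animal,
                   sub("\\.json$", "_per_animal.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a cohort
#'
#' [run_quantify()] then [aggregate_animals()] then [run_stats()].
#'
#' @inheritParams run_quantify
#' @inheritParams run_stats
#' @return A `study_report` with the per-image table attached as
#'   `$per_image`.
#' @export
run_pipeline <- function(cohort, cfg = seg_config(), out_dir = NULL,
                         band_frac = 0.25, alpha = 0.05) {
  per_image <- run_quantify(cohort, cfg, out_dir, band_frac)
  per_animal <- aggregate_animals(per_image)
  report <- run_stats(per_animal, alpha)
  report$per_image <- per_image
  report
}
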