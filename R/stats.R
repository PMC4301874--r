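# One-way ANOVA with Tukey's post-hoc test, from raw per-animal values or
# from published summary statistics (n, mean, SD). Implements the textbook
# sum-of-squares decomposition and the Tukey-Kramer generalization for
# unequal group sizes; tail probabilities come from pf() and ptukey().

#' Summarize one group of values
#'
#' @param values Numeric vector (at least 2 finite values).
#' @param label Group label.
#' @return A one-row data.frame: `label`, `n`, `mean`, `sd` (sample SD,
#'   n - 1 denominator).
#' @export
summarize_group <- function(values, label = "group") {
  values <- as.numeric(values)
  if (length(values) < 2 || !all(is.finite(values)))
    stop("need at least 2 finite values to summarize a group")
  data.frame(label = label, n = length(values), mean = mean(values),
             sd = stats::sd(values), stringsAsFactors = FALSE)
}

.check_summaries <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("label", "n", "mean", "sd") %in% names(groups)))
  if (nrow(groups) < 2) stop("need at least 2 groups")
  if (any(groups$n < 2)) stop("every group needs n >= 2")
  if (!all(is.finite(groups$mean)) || !all(is.finite(groups$sd)) ||
      any(groups$sd < 0))
    stop("group means must be finite and SDs finite and non-negative")
  groups
}

#' One-way ANOVA from group summary statistics
#'
#' Between-group sum of squares from the n-weighted grand mean,
#' within-group sum of squares from the sample SDs
#' (`ss_within = sum((n_i - 1) * sd_i^2)`), and the p-value from the upper
#' tail of the F distribution at (k - 1, N - k) degrees of freedom. This is
#' algebraically identical to the raw-data ANOVA, so printed "mean +/- SD"
#' tables reproduce published omnibus p-values exactly.
#'
#' @param groups data.frame with columns `label`, `n`, `mean`, `sd` (sample
#'   SD, n - 1 denominator).
#' @return An `anova_result`: list with `k_groups`, `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `F`, `p`, and a `degenerate`
#'   flag (TRUE when `ss_within` is 0 while means differ, in which case
#'   `p = 0`).
#' @export
anova_oneway_summary <- function(groups) {
  groups <- .check_summaries(groups)
  k <- nrow(groups); N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  dfb <- k - 1L; dfw <- N - k
  degenerate <- FALSE
  if (ssw == 0) {
    if (ssb == 0)
      stop("all group means equal with zero within-group variance: ",
           "the F statistic is undefined")
    degenerate <- TRUE
    Fst <- Inf; p <- 0
  } else {
    Fst <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(Fst, dfb, dfw, lower.tail = FALSE)
  }
  structure(list(k_groups = k, df_between = dfb, df_within = as.integer(dfw),
                 ss_between = ssb, ss_within = ssw, F = Fst, p = p,
                 ms_within = if (dfw > 0) ssw / dfw else NA_real_,
                 degenerate = degenerate, groups = groups),
            class = "anova_result")
}

#' One-way ANOVA from raw values
#'
#' @param values Named list of numeric vectors (>= 2 groups of >= 2 values)
#'   or a data.frame with columns `group` and `value`.
#' @return An `anova_result`; identical contract to
#'   [anova_oneway_summary()], to which it is algebraically equivalent.
#' @export
anova_oneway_raw <- function(values) {
  values <- .as_value_list(values)
  groups <- do.call(rbind, mapply(summarize_group, values, names(values),
                                  SIMPLIFY = FALSE))
  anova_oneway_summary(groups)
}

.as_value_list <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("group", "value") %in% names(values)))
    values <- split(values$value, values$group)
  }
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values)) || any(names(values) == ""))
    names(values) <- paste0("group", seq_along(values))
  values
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " [zero within-group variance]" else ""))
  invisible(x)
}

#' Tukey's honest significant difference (Tukey-Kramer)
#'
#' All pairwise group comparisons using the pooled within-group mean square
#' from the one-way ANOVA. For groups i, j:
#' `se = sqrt(MSw / 2 * (1/n_i + 1/n_j))`, `q = |m_i - m_j| / se`, and the
#' adjusted p-value is the upper tail of the studentized range distribution
#' with (k, df_within).
#'
#' @param groups Group summaries (data.frame `label`, `n`, `mean`, `sd`),
#'   a named list of raw value vectors, or a data.frame `group`/`value`.
#' @param alpha Family-wise significance level for the `significant` flag
#'   (default 0.05).
#' @return data.frame of comparisons: `group1`, `group2`, `mean_diff`
#'   (group2 - group1), `se`, `q`, `p_adj`, `significant`, `stars`; the
#'   ANOVA used for pooling is attached as attribute `"anova"`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (!is.data.frame(groups) || !"sd" %in% names(groups)) {
    groups <- do.call(rbind, mapply(summarize_group,
                                    .as_value_list(groups),
                                    names(.as_value_list(groups)),
                                    SIMPLIFY = FALSE))
  }
  an <- anova_oneway_summary(groups)
  k <- an$k_groups; dfw <- an$df_within; msw <- an$ms_within
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    diff <- groups$mean[j] - groups$mean[i]
    if (an$degenerate || msw == 0) {
      se <- 0
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      se <- sqrt(msw / 2 * (1 / groups$n[i] + 1 / groups$n[j]))
      q <- abs(diff) / se
      p <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
    }
    data.frame(group1 = groups$label[i], group2 = groups$label[j],
               mean_diff = diff, se = se, q = q, p_adj = p,
               significant = p < alpha, stars = stars(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "anova") <- an
  attr(out, "degenerate") <- an$degenerate
  out
}

#' Significance star codes
#'
#' The most extreme applicable of: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, otherwise `ns`. Inequalities are strict (p = 0.05 is
#' `ns`).
#'
#' @param p p-value(s) in \[0, 1\].
#' @return Character vector of codes.
#' @export
stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
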