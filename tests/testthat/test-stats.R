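test_that("group summaries: mean and sample SD", {
  s <- summarize_group(c(2, 4), "g")
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(summarize_group(rep(5, 4))$sd, 0)
  expect_error(summarize_group(3), "at least 2")
  set.seed(101)
  big <- summarize_group(rnorm(1000, 10, 2))
  expect_lt(abs(big$mean - 10), 0.2)
  expect_lt(abs(big$sd - 2), 0.2)
})

test_that("null and degenerate ANOVA cases", {
  eq <- data.frame(label = c("a", "b"), n = 4, mean = 5, sd = 1)
  r <- anova_oneway_summary(eq)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_equal(anova_oneway_raw(list(1:3, 1:3))$p, 1)
  deg <- anova_oneway_raw(list(c(0, 0), c(10, 10)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_error(anova_oneway_raw(list(c(1, 1), c(1, 1))), "undefined")
})

test_that("summary-statistic ANOVA equals raw-data ANOVA", {
  set.seed(5)
  for (i in 1:20) {
    vals <- random_groups(sample(2:5, 1))
    summ <- do.call(rbind, mapply(summarize_group, vals, names(vals),
                                  SIMPLIFY = FALSE))
    a1 <- anova_oneway_summary(summ)
    a2 <- anova_oneway_raw(vals)
    expect_equal(a1$F, a2$F, tolerance = 1e-10)
    expect_equal(a1$p, a2$p, tolerance = 1e-10)
  }
})

test_that("ANOVA agrees with the reference implementation on 50 random datasets", {
  set.seed(42)
  for (i in 1:50) {
    vals <- random_groups(sample(2:5, 1))
    d <- data.frame(value = unlist(vals),
                    group = rep(names(vals), lengths(vals)))
    ref <- anova(lm(value ~ group, data = d))
    mine <- anova_oneway_raw(vals)
    expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
    expect_equal(mine$df_within, ref$Df[2])
  }
})

test_that("F is invariant under shift and positive scaling", {
  set.seed(77)
  vals <- random_groups(4)
  f0 <- anova_oneway_raw(vals)$F
  expect_equal(anova_oneway_raw(lapply(vals, function(v) v + 13.7))$F, f0,
               tolerance = 1e-9)
  expect_equal(anova_oneway_raw(lapply(vals, function(v) v * 3.1))$F, f0,
               tolerance = 1e-9)
})

test_that("Tukey-Kramer agrees with the reference implementation", {
  set.seed(88)
  for (i in 1:20) {
    vals <- random_groups(4)
    d <- data.frame(value = unlist(vals),
                    group = factor(rep(names(vals), lengths(vals))))
    ref <- TukeyHSD(aov(value ~ group, data = d))$group
    mine <- tukey_hsd(vals)
    key <- paste(mine$group2, mine$group1, sep = "-")
    expect_equal(mine$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-4)
    expect_equal(mine$mean_diff, unname(ref[key, "diff"]), tolerance = 1e-8)
  }
})

test_that("two-group Tukey reduces to the pooled t-test (q = t * sqrt(2))", {
  set.seed(31)
  x <- rnorm(6, 5, 1); y <- rnorm(9, 6.2, 1.3)
  tk <- tukey_hsd(list(a = x, b = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$q, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-8)
})

test_that("Tukey adjustment never helps relative to the same-pooling pairwise test", {
  # the comparable unadjusted test uses the same pooled MSw and df_within;
  # against a plain two-sample t-test the inequality can fail under
  # variance heterogeneity because the pooling itself changes the SE
  set.seed(19)
  for (i in 1:10) {
    vals <- random_groups(4)
    tk <- tukey_hsd(vals)
    an <- attr(tk, "anova")
    for (r in seq_len(nrow(tk))) {
      p_pair <- 2 * pt(-tk$q[r] / sqrt(2), an$df_within)
      expect_gte(tk$p_adj[r] + 1e-12, p_pair)
    }
  }
})

test_that("equal group means give p_adj 1 and no significance", {
  g <- data.frame(label = c("a", "b", "c"), n = 5, mean = 4, sd = 1)
  tk <- tukey_hsd(g)
  expect_true(all(tk$p_adj > 1 - 1e-9))
  expect_false(any(tk$significant))
})

test_that("studentized-range tail matches a Monte-Carlo simulation", {
  k <- 4; df <- 12; q0 <- 3.0
  set.seed(202)
  nrep <- 40000
  z <- matrix(rnorm(nrep * k), nrep, k)
  s <- sqrt(rchisq(nrep, df) / df)
  qs <- (apply(z, 1, max) - apply(z, 1, min)) / s
  mc <- mean(qs > q0)
  expect_lt(abs(mc - ptukey(q0, k, df, lower.tail = FALSE)), 0.01)
})

test_that("star codes follow the strict thresholds", {
  expect_identical(stars(c(0.04, 0.0005, 0.05, 0.009, 0.2)),
                   c("*", "***", "ns", "**", "ns"))
  expect_error(stars(1.2), "\\[0, 1\\]")
  expect_error(stars(-0.1), "\\[0, 1\\]")
})
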