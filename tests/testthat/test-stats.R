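groups_df <- function(...) {
  vals <- list(...)
  tibble::tibble(
    grade = rep(paste0("G", seq_along(vals) - 1), lengths(vals)),
    brc = unlist(vals)
  )
}

test_that("degenerate identical groups give F = 0, p = 1 and all-ns Tukey", {
  df <- groups_df(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  a <- oneway_anova(df)
  expect_equal(a$statistic, 0)
  expect_equal(a$p.value, 1)
  tk <- tukey_hsd(df)
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$adj.p.value == 1))
  expect_true(all(tk$class == "ns"))
  vh <- variance_homogeneity(df)
  expect_equal(vh$p.value, 1)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(8, {
    for (i in 1:10) {
      x <- rnorm(9); y <- rnorm(7, mean = 0.8)
      df <- groups_df(x, y)
      f <- oneway_anova(df)$statistic
      t2 <- unname(stats::t.test(x, y, var.equal = TRUE)$statistic)^2
      expect_equal(f, t2, tolerance = 1e-10)
    }
  })
})

test_that("Tukey adjustment never reports smaller p than the unadjusted pairwise test", {
  withr::with_seed(12, {
    for (i in 1:8) {
      df <- groups_df(rnorm(10, 3, 0.5), rnorm(8, 1.7, 0.4), rnorm(8, 1.8, 0.7))
      tk <- tukey_hsd(df)
      # unadjusted pooled-variance pairwise tests
      fit <- aov(brc ~ factor(grade), data = df)
      mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
      dfw <- summary(fit)[[1]]["Residuals", "Df"]
      means <- tapply(df$brc, df$grade, mean)
      ns <- tapply(df$brc, df$grade, length)
      pairs <- utils::combn(names(means), 2)
      for (k in seq_len(ncol(pairs))) {
        g1 <- pairs[1, k]; g2 <- pairs[2, k]
        tstat <- (means[g2] - means[g1]) /
          sqrt(mse * (1 / ns[g1] + 1 / ns[g2]))
        p_un <- 2 * pt(-abs(tstat), dfw)
        p_adj <- tk$adj.p.value[tk$comparison == paste0(g2, "-", g1)]
        expect_gte(p_adj + 1e-12, p_un)
      }
    }
  })
})

test_that("insufficient data is rejected", {
  expect_error(oneway_anova(groups_df(c(1, 2), c(3))),
               class = "psoct_insufficient_data")
  expect_error(oneway_anova(tibble::tibble(grade = "G0", brc = 1)),
               class = "psoct_insufficient_data")
  expect_error(oneway_anova(groups_df(c(1, NA, 2), c(1, 2))),
               class = "psoct_insufficient_data")
})

test_that("variance homogeneity flags a 5x SD ratio at n = 10 in most seeds", {
  rejected <- sapply(1:30, function(s) {
    withr::with_seed(1000 + s, {
      df <- groups_df(rnorm(10, 0, 1), rnorm(10, 0, 5), rnorm(10, 0, 1))
    })
    variance_homogeneity(df)$p.value <= 0.05
  })
  expect_gt(mean(rejected), 0.5)
})

test_that("variance homogeneity holds its size under equal variances", {
  p <- sapply(1:400, function(s) {
    withr::with_seed(5000 + s, {
      df <- groups_df(rnorm(10), rnorm(8), rnorm(8))
    })
    variance_homogeneity(df)$p.value
  })
  expect_equal(mean(p <= 0.05), 0.05, tolerance = 0.6)
  expect_gt(mean(p <= 0.05), 0.005)
})

test_that("vectorised null ANOVA matches stats::oneway.test", {
  withr::with_seed(2, {
    g <- rep(c("a", "b", "c"), c(10, 8, 8))
    y <- matrix(rnorm(26 * 5), nrow = 5)
  })
  pv <- psoct:::oneway_anova_pvec(y, g)
  ref <- apply(y, 1, function(r) stats::oneway.test(r ~ g, var.equal = TRUE)$p.value)
  expect_equal(pv, ref, tolerance = 1e-12)
})

test_that("normality check reports one row per group", {
  withr::with_seed(3, df <- groups_df(rnorm(10), rnorm(8), rnorm(8)))
  nr <- normality_check(df)
  expect_equal(nrow(nr), 3)
  expect_true(all(nr$p.value > 0 & nr$p.value <= 1))
})

test_that("study summary reproduces exact group means and the table layout", {
  # zero-SD presets: the observed group means are exactly the preset means
  samples <- grade_presets() |>
    tidyr::uncount(3, .id = "rep") |>
    dplyr::mutate(brc = brc_mean + 0.001 * rep) |>  # tiny jitter, keeps SD equal
    dplyr::select(grade, config, brc)
  sm <- summarize_study(samples)
  gs <- sm$group_stats
  for (cf in psoct_configs()) for (g in psoct_grades()) {
    expect_equal(gs$mean[gs$config == cf & gs$grade == g],
                 grade_presets()$brc_mean[grade_presets()$config == cf &
                                            grade_presets()$grade == g] + 0.002,
                 tolerance = 1e-12)
  }
  # column order follows the published table: indented, non-indented, XY
  expect_equal(names(sm$table), c("row", "XZ_indented", "XZ_nonindented", "XY"))
  expect_equal(sm$table$row[1:4], c("G0", "G1", "G2", "Anova P-value"))
  expect_equal(sm$table$row[5:7],
               c("G0 vs. G1", "G0 vs. G2", "G1 vs. G2"))
  expect_error(summarize_study(dplyr::filter(samples, config != "XY")),
               class = "psoct_structural_error")
  expect_output(print(sm), "Anova P-value")
})

test_that("significance legend matches the published thresholds", {
  expect_equal(significance_class(c(0.0005, 0.001, 0.005, 0.03, 0.05, 0.2)),
               c("***", "***", "**", "*", "*", "ns"))
})
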