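#' Significance classes used in the study tables
#'
#' `***` for p <= 0.001, `**` for 0.001 < p <= 0.01, `*` for
#' 0.01 < p <= 0.05 (the global significance cut), `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of significance labels.
#' @export
significance_class <- function(p) {
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

check_groups <- function(data, value, group) {
  if (!all(c(value, group) %in% names(data))) {
    stop_psoct(paste0("data must have columns '", value, "' and '", group, "'"),
               "psoct_structural_error")
  }
  v <- data[[value]]
  if (anyNA(v) || any(!is.finite(v))) {
    stop_psoct("group values must be finite and non-missing", "psoct_insufficient_data")
  }
  counts <- table(data[[group]])
  if (length(counts) < 2 || any(counts < 2)) {
    stop_psoct("need >= 2 groups with >= 2 values each", "psoct_insufficient_data")
  }
  invisible(data)
}

#' One-way fixed-effects ANOVA across grade groups
#'
#' Classical one-way ANOVA of a per-sample value (typically the recovered
#' BRC) across groups. With two groups the F statistic equals the square of
#' the pooled two-sample t statistic. Degenerate all-equal data yield
#' `F = 0`, `p = 1`.
#'
#' @param data A data frame with one row per specimen.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor. Defaults `"brc"` and `"grade"`.
#' @return A one-row tibble: `statistic` (F), `p.value`, `df_between`,
#'   `df_within`.
#' @export
oneway_anova <- function(data, value = "brc", group = "grade") {
  check_groups(data, value, group)
  g <- factor(data[[group]])
  y <- data[[value]]
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  f <- unname(fit$statistic)
  p <- unname(fit$p.value)
  if (is.nan(f)) { f <- 0; p <- 1 }  # zero within- and between-group variance
  tibble::tibble(
    statistic = f, p.value = p,
    df_between = unname(fit$parameter[1]),
    df_within = unname(fit$parameter[2])
  )
}

#' Tukey HSD post-hoc comparisons
#'
#' Studentized-range-adjusted pairwise comparisons following a one-way
#' ANOVA, with decisions at `alpha` and the study's significance legend.
#'
#' @inheritParams oneway_anova
#' @param alpha Significance level for the decision column. Default 0.05.
#' @return A tibble with one row per pair: `comparison`, `estimate`
#'   (difference of means), `conf.low`, `conf.high`, `adj.p.value`,
#'   `significant`, `class`.
#' @export
tukey_hsd <- function(data, value = "brc", group = "grade", alpha = 0.05) {
  check_groups(data, value, group)
  df <- data.frame(y = data[[value]], g = factor(data[[group]]))
  fit <- aov(y ~ g, data = df)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  # identical groups give 0/0 -> NaN; no evidence of a difference
  adj <- ifelse(is.nan(tk[, "p adj"]), 1, tk[, "p adj"])
  tibble::tibble(
    comparison = rownames(tk),
    estimate = unname(tk[, "diff"]),
    conf.low = unname(tk[, "lwr"]),
    conf.high = unname(tk[, "upr"]),
    adj.p.value = unname(adj),
    significant = unname(adj) <= alpha,
    class = significance_class(unname(adj))
  )
}

#' Bartlett test of variance homogeneity
#'
#' Reported alongside the ANOVA as the published analysis does; it does not
#' gate the ANOVA.
#'
#' @inheritParams oneway_anova
#' @return A one-row tibble: `statistic`, `p.value`, `df`.
#' @export
variance_homogeneity <- function(data, value = "brc", group = "grade") {
  check_groups(data, value, group)
  g <- factor(data[[group]])
  y <- data[[value]]
  if (all(vapply(split(y, g), function(v) isTRUE(all.equal(sd(v), 0)), TRUE)) ||
      isTRUE(all.equal(stats::var(y), 0))) {
    return(tibble::tibble(statistic = 0, p.value = 1, df = nlevels(g) - 1))
  }
  fit <- bartlett.test(y ~ g)
  tibble::tibble(statistic = unname(fit$statistic),
                 p.value = unname(fit$p.value),
                 df = unname(fit$parameter))
}

#' Shapiro-Wilk normality check per group
#'
#' Reporting-only, as in the published analysis.
#'
#' @inheritParams oneway_anova
#' @return A tibble with one row per group: `group`, `statistic`, `p.value`
#'   (`NA` for degenerate all-equal groups).
#' @export
normality_check <- function(data, value = "brc", group = "grade") {
  check_groups(data, value, group)
  data |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      statistic = tryCatch(shapiro.test(.data[[value]])$statistic,
                           error = function(e) NA_real_),
      p.value = tryCatch(shapiro.test(.data[[value]])$p.value,
                         error = function(e) NA_real_),
      .groups = "drop"
    )
}

# fast vectorised one-way ANOVA p-values for B response matrices sharing one
# grouping vector (rows = replicates); used by the Monte-Carlo calibration.
# Cross-checked against stats::oneway.test in the tests.
oneway_anova_pvec <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- length(g)
  gm <- rowMeans(y)
  ssb <- 0
  ssw <- 0
  for (lev in levels(g)) {
    cols <- which(g == lev)
    m <- rowMeans(y[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * (m - gm)^2
    ssw <- ssw + rowSums((y[, cols, drop = FALSE] - m)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' Summarise a three-configuration study in the published table layout
#'
#' Takes the per-sample results of a full simulated study (all three imaging
#' configurations) and emits the group means and SDs, the per-configuration
#' one-way ANOVA p-value, and the Tukey post-hoc significance classes, laid
#' out with configurations as columns in the order indented, non-indented,
#' XY.
#'
#' @param samples A data frame with columns `grade`, `config`, `brc` (one
#'   row per specimen per configuration).
#' @param alpha Significance level. Default 0.05.
#' @return An object of class `study_summary`: a list of tibbles
#'   `group_stats`, `anova`, `tukey`, `homogeneity`, `normality` and the
#'   formatted `table` (character columns, one per configuration).
#' @export
summarize_study <- function(samples, alpha = 0.05) {
  if (!all(psoct_configs() %in% samples$config)) {
    stop_psoct("samples must cover all three imaging configurations",
               "psoct_structural_error")
  }
  cfgs <- psoct_configs()
  by_cfg <- purrr::map(setNames(cfgs, cfgs), function(cf) {
    dplyr::filter(samples, .data$config == cf)
  })

  group_stats <- samples |>
    dplyr::group_by(.data$config, .data$grade) |>
    dplyr::summarise(mean = mean(.data$brc), sd = sd(.data$brc),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(config = factor(.data$config, levels = cfgs)) |>
    dplyr::arrange(.data$config, .data$grade)

  anova <- purrr::map(by_cfg, oneway_anova) |>
    dplyr::bind_rows(.id = "config")
  tukey <- purrr::map(by_cfg, tukey_hsd, alpha = alpha) |>
    dplyr::bind_rows(.id = "config")
  homogeneity <- purrr::map(by_cfg, variance_homogeneity) |>
    dplyr::bind_rows(.id = "config")
  normality <- purrr::map(by_cfg, normality_check) |>
    dplyr::bind_rows(.id = "config")

  cell <- function(cf, gr) {
    s <- dplyr::filter(group_stats, .data$config == cf, .data$grade == gr)
    sprintf("%.1f ± %.1f", s$mean, s$sd)
  }
  pcell <- function(cf) {
    p <- anova$p.value[anova$config == cf]
    if (p < 0.001) "<0.001" else sprintf("%.3f", p)
  }
  starcell <- function(cf, pair) {
    tk <- dplyr::filter(tukey, .data$config == cf, .data$comparison == pair)
    tk$class
  }
  pairs <- sort(unique(tukey$comparison))
  pair_label <- vapply(strsplit(pairs, "-"), function(p) {
    paste(rev(p), collapse = " vs. ")
  }, "")
  table <- tibble::tibble(
    row = c(psoct_grades(), "Anova P-value", pair_label),
    XZ_indented = c(vapply(psoct_grades(), cell, "", cf = "XZ_indented"),
                    pcell("XZ_indented"),
                    vapply(pairs, starcell, "", cf = "XZ_indented")),
    XZ_nonindented = c(vapply(psoct_grades(), cell, "", cf = "XZ_nonindented"),
                       pcell("XZ_nonindented"),
                       vapply(pairs, starcell, "", cf = "XZ_nonindented")),
    XY = c(vapply(psoct_grades(), cell, "", cf = "XY"),
           pcell("XY"),
           vapply(pairs, starcell, "", cf = "XY"))
  )

  structure(
    list(group_stats = group_stats, anova = anova, tukey = tukey,
         homogeneity = homogeneity, normality = normality, table = table),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Retardation gradient (rad/mm), mean ± SD by grade and imaging plane\n\n")
  df <- as.data.frame(x$table)
  names(df) <- c("", "XZ - Indented", "XZ - Non-indented", "XY")
  print(df, row.names = FALSE, right = FALSE)
  cat("\n*** p <= 0.001, ** 0.001 < p <= 0.01, * 0.01 < p <= 0.05, ns not significant\n")
  invisible(x)
}
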