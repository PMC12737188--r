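# Statistics layer: Pearson correlation with the t-transform two-tailed
# p-value, pooled-variance t test and one-way ANOVA, Gaussian moment fits,
# and assembly of the per-experiment summary report.

#' Two-tailed p-value from a Pearson correlation
#'
#' Under the null of zero correlation, `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' follows a t distribution with `n - 2` degrees of freedom; the two-tailed
#' p-value is twice its upper tail at `|t|`. `|r| = 1` returns `p = 0` by
#' convention. Vectorized over `r`.
#'
#' @param r Correlation coefficient(s), `|r| <= 1`.
#' @param n Sample size (>= 3).
#' @return p-value(s) in `[0, 1]`.
#' @export
p_from_r <- function(r, n) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  p <- rep(0, length(r))
  sub <- abs(r) < 1
  t_stat <- abs(r[sub]) * sqrt(n - 2) / sqrt(1 - r[sub]^2)
  p[sub] <- 2 * pt(t_stat, df = n - 2, lower.tail = FALSE)
  p
}

#' Pearson correlation with significance
#'
#' Product-moment correlation with the two-tailed t-transform p-value and an
#' explicit significance flag at level `alpha`.
#'
#' @param x,y Paired numeric samples, `n >= 3`, finite, nonzero variance.
#' @param alpha Significance level (default 0.05).
#' @return A `correlation_result` list: `r`, `n`, `t_stat`, `p_two_tailed`,
#'   `alpha`, `significant`.
#' @export
pearson_cor <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- max(-1, min(1, r))
  t_stat <- if (abs(r) < 1) r * sqrt(n - 2) / sqrt(1 - r^2) else sign(r) * Inf
  p <- p_from_r(r, n)
  structure(list(r = r, n = n, t_stat = t_stat, p_two_tailed = p,
                 alpha = alpha, significant = p < alpha),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d), t = %.3f, two-tailed p = %.4g%s\n",
              x$r, x$n, x$t_stat, x$p_two_tailed,
              if (x$significant) sprintf(" (significant at alpha = %g)", x$alpha)
              else ""))
  invisible(x)
}

#' Compare groups by t test or one-way ANOVA
#'
#' `test = "t"`: Student two-sample t with pooled variance (Welch available
#' via `var_equal = FALSE`), two-tailed. `test = "anova"`: one-way ANOVA F
#' with upper-tail p.
#'
#' @param groups A list of numeric vectors (exactly 2 for `"t"`, >= 2 for
#'   `"anova"`), each with at least 2 values.
#' @param test `"t"` or `"anova"`.
#' @param var_equal Pooled variance for the t test? Default `TRUE`.
#' @return A `group_comparison_result` list: `test`, `statistic`, `df`,
#'   `p_two_tailed`, `group_means`, `group_sds`.
#' @export
compare_groups <- function(groups, test = c("t", "anova"), var_equal = TRUE) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs at least 2 values", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, sd, numeric(1))

  if (test == "t") {
    if (length(groups) != 2)
      stop("t test requires exactly 2 groups", call. = FALSE)
    x <- groups[[1]]; y <- groups[[2]]
    n1 <- ns[1]; n2 <- ns[2]
    if (var_equal) {
      sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      se <- sqrt(var(x) / n1 + var(y) / n2)
      df <- se^4 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
    }
    stat <- if (se == 0) 0 else (mean(x) - mean(y)) / se
    p <- 2 * pt(abs(stat), df = df, lower.tail = FALSE)
  } else {
    k <- length(groups)
    all_v <- unlist(groups)
    n <- length(all_v)
    grand <- mean(all_v)
    ss_between <- sum(ns * (means - grand)^2)
    ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                            numeric(1)))
    df <- c(between = k - 1, within = n - k)
    ms_b <- ss_between / df[1]; ms_w <- ss_within / df[2]
    stat <- if (ms_w == 0) { if (ms_b == 0) 0 else Inf } else ms_b / ms_w
    p <- pf(stat, df[1], df[2], lower.tail = FALSE)
  }
  structure(list(test = test, statistic = as.numeric(stat),
                 df = as.numeric(df), p_two_tailed = as.numeric(p),
                 group_means = means, group_sds = sds),
            class = "group_comparison_result")
}

#' Gaussian moment fit
#'
#' Maximum-likelihood mean and SD of a Gaussian (the ML SD uses the n
#' denominator; the n-1 sample SD is reported alongside).
#'
#' @param samples Numeric vector, `n >= 2`.
#' @return List: `mean`, `sd_ml` (n denominator), `sd_sample` (n-1), `n`.
#' @export
fit_gaussian <- function(samples) {
  x <- as.numeric(samples)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("samples must be finite", call. = FALSE)
  n <- length(x)
  m <- mean(x)
  list(mean = m, sd_ml = sqrt(sum((x - m)^2) / n), sd_sample = sd(x), n = n)
}

mean_sd_block <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
       n = length(x))
}

#' Assemble the summary report
#'
#' Computes the descriptive block (mean ± SD across cells/aggregates of
#' colocalization fraction, aggregate size, NP volume fraction and aggregate
#' count), the three uptake correlations (cell volume vs total NP volume;
#' total NP volume vs mean cell RI; mean aggregate size vs mean cell RI —
#' zero-aggregate cells are excluded from the third, where a mean aggregate
#' size is undefined), and the two distribution summaries (Gaussian fit of
#' counts per cell; aggregate size histogram with cumulative curve and
#' fraction below 1 µm³).
#'
#' @param cells Per-cell statistics table from [compute_cell_stats()].
#' @param aggregates Aggregate table from [detect_aggregates()].
#' @param coloc Optional per-cell colocalization table from
#'   [coloc_per_cell()] (`$per_cell`), or `NULL` when no fluorescence channel
#'   exists.
#' @param alpha Significance level for the correlations (default 0.05).
#' @param size_cutoff_um3 Cutoff for the small-aggregate fraction (default 1).
#' @return A `summary_report` list with `descriptives`, `correlations`,
#'   `distributions`; missing inputs yield explicit `NA` fields.
#' @export
build_report <- function(cells, aggregates, coloc = NULL, alpha = 0.05,
                         size_cutoff_um3 = 1) {
  stopifnot(is.data.frame(cells), is.data.frame(aggregates))
  in_cell <- aggregates[aggregates$cell_id > 0L, , drop = FALSE]

  descriptives <- list(
    colocalization_pct = if (!is.null(coloc))
      mean_sd_block(coloc$fluor_in_high_ri_fraction)
    else list(mean = NA_real_, sd = NA_real_, n = 0L),
    aggregate_size_um3 = mean_sd_block(in_cell$volume_um3),
    np_volume_fraction_pct = mean_sd_block(cells$np_volume_fraction),
    aggregates_per_cell = mean_sd_block(cells$aggregate_count),
    n_cells = nrow(cells),
    n_aggregates = nrow(in_cell))

  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NULL)
    unclass(pearson_cor(x[ok], y[ok], alpha))
  }
  with_agg <- cells[cells$aggregate_count > 0, , drop = FALSE]
  correlations <- list(
    cell_volume_vs_np_volume =
      safe_cor(cells$cell_volume_um3, cells$total_np_volume_um3),
    np_volume_vs_mean_ri =
      safe_cor(cells$total_np_volume_um3, cells$mean_cell_ri),
    mean_aggregate_size_vs_mean_ri =
      safe_cor(with_agg$mean_aggregate_volume_um3, with_agg$mean_cell_ri))

  distributions <- list(
    counts_gaussian_fit = if (nrow(cells) >= 2)
      fit_gaussian(cells$aggregate_count) else NULL,
    aggregate_sizes = if (nrow(in_cell) >= 1)
      aggregate_size_distribution(in_cell, cutoff_um3 = size_cutoff_um3)
    else NULL)

  structure(list(descriptives = descriptives, correlations = correlations,
                 distributions = distributions, alpha = alpha),
            class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  d <- x$descriptives
  fmt <- function(b, unit = "") {
    if (is.na(b$mean)) "missing"
    else sprintf("%.3g ± %.3g%s (n = %d)", b$mean, b$sd, unit, b$n)
  }
  cat("Summary report\n")
  cat("  colocalization (fluor in high-RI): ", fmt(d$colocalization_pct, "%"),
      "\n", sep = "")
  cat("  aggregate size:                    ",
      fmt(d$aggregate_size_um3, " um^3"), "\n", sep = "")
  cat("  NP volume fraction:                ",
      fmt(d$np_volume_fraction_pct, "%"), "\n", sep = "")
  cat("  aggregates per cell:               ", fmt(d$aggregates_per_cell),
      "\n", sep = "")
  for (nm in names(x$correlations)) {
    cr <- x$correlations[[nm]]
    if (is.null(cr)) next
    cat(sprintf("  %s: r = %.4f, p = %.4g\n", nm, cr$r, cr$p_two_tailed))
  }
  invisible(x)
}
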