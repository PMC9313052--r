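#' Mean and standard error of the mean
#'
#' SEM is the sample standard deviation (n-1 denominator) divided by
#' sqrt(n); a single observation has SEM 0 by convention, as do ties.
#'
#' @param values Non-empty numeric vector.
#' @return A list with `mean` and `sem`.
#' @export
mean_sem <- function(values) {
  if (length(values) == 0) stop("mean_sem: empty input")
  s <- if (length(values) == 1) 0 else stats::sd(values) / sqrt(length(values))
  list(mean = mean(values), sem = s)
}

#' Per-stratum summary (mean +/- SEM) of per-sample counts
#'
#' Strata are the four group-by-morphology combinations (non-COPD N/R,
#' COPD N/R). Every stratum present in the input must contain at least one
#' sample.
#'
#' @param per_sample Data frame with `group`, `morphology` and the metric
#'   columns.
#' @param metrics Character vector of metric column names to summarize.
#' @return A data frame with columns `group`, `morphology`, `metric`, `n`,
#'   `mean`, `sem`.
#' @export
stratum_summary <- function(per_sample, metrics) {
  rows <- list()
  for (g in rp_groups) {
    for (mo in rp_morphologies) {
      sel <- per_sample$group == g & per_sample$morphology == mo
      if (!any(sel)) {
        stop("empty stratum: ", g, " ", mo)
      }
      for (met in metrics) {
        ms <- mean_sem(per_sample[[met]][sel])
        rows[[length(rows) + 1]] <- data.frame(
          group = g, morphology = mo, metric = met, n = sum(sel),
          mean = ms$mean, sem = ms$sem, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Two-sample t-test with zero-variance guards
#'
#' Pooled-variance (Student) t-test by default, with df = n_a + n_b - 2;
#' Welch's unequal-variance form with `equal_var = FALSE`. Degenerate
#' inputs are handled explicitly: when both samples are constant the test
#' returns p = 1 for equal means and the p -> 0 limit (flagged in
#' `degenerate`) for unequal means.
#'
#' @param a,b Numeric vectors with at least 2 observations each.
#' @param equal_var Pool the variances (default TRUE).
#' @param label Contrast label carried into the result.
#' @return A list with `contrast`, `t`, `df`, `p`, `significant`
#'   (p < 0.05) and `degenerate`.
#' @export
two_sample_t <- function(a, b, equal_var = TRUE, label = "a_vs_b") {
  if (length(a) < 2 || length(b) < 2) {
    stop("two_sample_t: each sample needs at least 2 observations")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(contrast = label, t = 0, df = length(a) + length(b) - 2,
                  p = 1, significant = FALSE, degenerate = FALSE))
    }
    return(list(contrast = label, t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0, significant = TRUE,
                degenerate = TRUE))
  }
  fit <- stats::t.test(a, b, var.equal = equal_var)
  list(contrast = label, t = unname(fit$statistic),
       df = unname(fit$parameter), p = fit$p.value,
       significant = fit$p.value < 0.05, degenerate = FALSE)
}

#' Fold change between two group means
#'
#' Ratio of the target mean over the reference mean, rounded half-up to
#' one decimal, the precision at which fold increases are reported.
#'
#' @param mean_target,mean_reference Group means; the reference must be
#'   strictly positive.
#' @return The rounded ratio.
#' @examples
#' fold_change(244.7, 100.3)  # 2.4
#' fold_change(157.7, 100.3)  # 1.6
#' @export
fold_change <- function(mean_target, mean_reference) {
  if (mean_reference <= 0) stop("fold_change: reference mean must be > 0")
  round_half_up(mean_target / mean_reference, 1)
}

## round() uses banker's rounding; reported ratios and percentages use
## conventional half-up instead, so 2.45 -> 2.5.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement, preserving
#' the input order. Input p-values must lie in (0, 1].
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Significance stars for report tables
#'
#' @param p Numeric vector of p-values.
#' @return `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Pairwise stratum t-tests on a per-sample metric
#'
#' Runs [two_sample_t()] for each stratum against the non-COPD N baseline
#' and for the within-group N-vs-R contrasts, the comparisons underlying
#' the reported fold increases.
#'
#' @param per_sample Per-sample count frame (from [count_variants()] or
#'   [count_cna()]).
#' @param metric Metric column name.
#' @param equal_var Pool variances (default TRUE, Student's form).
#' @return A data frame with columns `contrast`, `t`, `df`, `p`, `star`,
#'   `fold_change`.
#' @export
stratum_tests <- function(per_sample, metric, equal_var = TRUE) {
  val <- function(g, mo) {
    per_sample[[metric]][per_sample$group == g & per_sample$morphology == mo]
  }
  contrasts <- list(
    c("NON_COPD", "R", "NON_COPD", "N"),
    c("COPD", "N", "NON_COPD", "N"),
    c("COPD", "R", "NON_COPD", "N"),
    c("COPD", "R", "COPD", "N"))
  rows <- list()
  for (ct in contrasts) {
    a <- val(ct[1], ct[2]); b <- val(ct[3], ct[4])
    label <- paste0(ct[1], "_", ct[2], "_vs_", ct[3], "_", ct[4])
    tt <- two_sample_t(a, b, equal_var = equal_var, label = label)
    fc <- if (mean(b) > 0) fold_change(mean(a), mean(b)) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      contrast = label, t = tt$t, df = tt$df, p = tt$p,
      star = significance_stars(tt$p), fold_change = fc,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
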