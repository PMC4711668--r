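## Quality-metric panel for HTS control plates.
##
## All location/scale summaries use the sample conventions: sd with the
## n-1 denominator, median absolute deviation scaled by 1.4826 (the
## reciprocal of qnorm(3/4)) so that MAD estimates sigma under
## normality.

MAD_CONSTANT <- 1.4826

METRIC_IDS <- c("z_prime", "ssmd_mm", "ssmd_mle", "ssmd_robust",
                "t_stat", "t_pvalue", "ks_stat",
                "sb_ratio", "sn_ratio", "cv_pos", "cv_neg")

## Direction used when ranking assays: +1 means larger is better.
METRIC_DIRECTIONS <- c(z_prime = 1, ssmd_mm = 1, ssmd_mle = 1,
                       ssmd_robust = 1, t_stat = 1, t_pvalue = -1,
                       ks_stat = 1, sb_ratio = 1, sn_ratio = 1,
                       cv_pos = -1, cv_neg = -1)

as_control_groups <- function(cg) {
  if (inherits(cg, "control_groups")) return(cg)
  if (inherits(cg, "plate_assay")) return(extract_controls(cg))
  input_error("expected a control_groups (or plate_assay) object")
}

check_group_sizes <- function(cg, min_n = 2L, metric = "metric") {
  if (length(cg$pos) < min_n || length(cg$neg) < min_n)
    undefined_metric(metric, sprintf(
      "both control groups need n >= %d (got %d and %d)",
      min_n, length(cg$pos), length(cg$neg)))
}

#' Location/scale summary of one control group
#'
#' Computes the sample size, mean, sample standard deviation (n-1
#' denominator), median and scaled median absolute deviation
#' `1.4826 * median(|x_i - m|)`.  For a single observation the standard
#' deviation and MAD are undefined and reported as `NA`.
#'
#' @param values Non-empty numeric vector of finite readouts.
#' @return An object of class `group_summary` with fields `n`, `mean`,
#'   `sd`, `median`, `mad`.
#' @examples
#' summarize_group(c(1, 2, 3))
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) input_error("cannot summarize an empty vector")
  if (any(!is.finite(values)))
    input_error("readouts must all be finite")
  n <- length(values)
  structure(list(
    n = n,
    mean = mean(values),
    sd = if (n >= 2L) stats::sd(values) else NA_real_,
    median = stats::median(values),
    mad = if (n >= 2L) stats::mad(values, constant = MAD_CONSTANT)
          else NA_real_
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.6g, sd = %s, median = %.6g, mad = %s\n",
              x$n, x$mean, format(x$sd), x$median, format(x$mad)))
  invisible(x)
}

#' Z'-factor of an assay
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`: the fraction
#' of the control separation band left free after carving out three
#' standard deviations around each control mean.  At most 1, reached
#' only when both groups have zero spread; non-positive values mean the
#' 3-sigma bands overlap.
#'
#' @param cg A [control_groups()] object (or an endpoint `plate_assay`,
#'   from which controls are extracted).
#' @return The Z'-factor, a number `<= 1`.
#' @examples
#' z_prime(control_groups(c(9, 10, 11), c(1, 2, 3)))  # 0.25
#' @export
z_prime <- function(cg) {
  cg <- as_control_groups(cg)
  check_group_sizes(cg, metric = "z_prime")
  mu_d <- mean(cg$pos) - mean(cg$neg)
  if (mu_d == 0)
    undefined_metric("z_prime", "positive and negative means are equal")
  1 - 3 * (stats::sd(cg$pos) + stats::sd(cg$neg)) / abs(mu_d)
}

#' Strictly standardized mean difference, method-of-moments estimator
#'
#' `beta_MM = (mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2)` with
#' sample (n-1) variances.
#'
#' @inheritParams z_prime
#' @return The SSMD estimate; shares the sign of the mean difference.
#' @export
ssmd_mm <- function(cg) {
  cg <- as_control_groups(cg)
  check_group_sizes(cg, metric = "ssmd_mm")
  denom2 <- stats::var(cg$pos) + stats::var(cg$neg)
  if (denom2 == 0)
    undefined_metric("ssmd_mm", "both groups have zero variance")
  (mean(cg$pos) - mean(cg$neg)) / sqrt(denom2)
}

#' Strictly standardized mean difference, maximum-likelihood estimator
#'
#' Same contrast as [ssmd_mm()] but with the maximum-likelihood
#' variances `sd^2 (n-1)/n`, i.e.
#' `beta_MLE = (mean_pos - mean_neg) /
#'   sqrt(sd_pos^2 (n_pos-1)/n_pos + sd_neg^2 (n_neg-1)/n_neg)`.
#' Always at least as large in magnitude as `beta_MM` on the same data,
#' converging to it as the group sizes grow.
#'
#' @inheritParams z_prime
#' @export
ssmd_mle <- function(cg) {
  cg <- as_control_groups(cg)
  check_group_sizes(cg, metric = "ssmd_mle")
  np <- length(cg$pos); nn <- length(cg$neg)
  denom2 <- stats::var(cg$pos) * (np - 1) / np +
            stats::var(cg$neg) * (nn - 1) / nn
  if (denom2 == 0)
    undefined_metric("ssmd_mle", "both groups have zero variance")
  (mean(cg$pos) - mean(cg$neg)) / sqrt(denom2)
}

#' Strictly standardized mean difference, robust (median/MAD) estimator
#'
#' `beta_R = (median_pos - median_neg) / sqrt(MAD_pos^2 + MAD_neg^2)`
#' with the 1.4826-scaled median absolute deviation.  Because median and
#' MAD have a 50% breakdown point, this variant resists the outliers
#' that collapse the moment-based estimators.
#'
#' @inheritParams z_prime
#' @export
ssmd_robust <- function(cg) {
  cg <- as_control_groups(cg)
  check_group_sizes(cg, metric = "ssmd_robust")
  mad_p <- stats::mad(cg$pos, constant = MAD_CONSTANT)
  mad_n <- stats::mad(cg$neg, constant = MAD_CONSTANT)
  denom2 <- mad_p^2 + mad_n^2
  if (denom2 == 0)
    undefined_metric("ssmd_robust", "both groups have zero MAD")
  (stats::median(cg$pos) - stats::median(cg$neg)) / sqrt(denom2)
}

#' Welch's two-sample t statistic
#'
#' Two-sided t test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), as provided by
#' [stats::t.test()].
#'
#' @inheritParams z_prime
#' @return A list with components `t`, `df` and `p`.
#' @examples
#' welch_t(control_groups(c(9, 10, 11), c(1, 2, 3)))
#' @export
welch_t <- function(cg) {
  cg <- as_control_groups(cg)
  check_group_sizes(cg, metric = "t_stat")
  if (stats::var(cg$pos) == 0 && stats::var(cg$neg) == 0) {
    if (mean(cg$pos) == mean(cg$neg))
      return(list(t = 0, df = NA_real_, p = 1))
    undefined_metric("t_stat", "both groups have zero variance")
  }
  fit <- stats::t.test(cg$pos, cg$neg, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximum absolute distance between the empirical cumulative
#' distribution functions of two samples, evaluated at the sorted
#' pooled unique values (both ECDFs are right-continuous step
#' functions, so this grid attains the supremum).  The two-sided
#' statistic lies in `[0, 1]`; it equals 1 exactly when the sample
#' ranges do not overlap, and is invariant under any strictly
#' increasing transform applied to both samples.  Only the statistic is
#' computed, not a p-value.
#'
#' @param a,b Non-empty numeric vectors.
#' @return The KS distance in `[0, 1]`.
#' @examples
#' ks_stat(c(1, 3), c(2, 4))  # 0.5
#' @export
ks_stat <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b))
    input_error("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    input_error("samples must be finite")
  grid <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(grid)
  fb <- stats::ecdf(b)(grid)
  max(abs(fa - fb))
}

#' Signal-to-background ratio
#'
#' `S/B = mean_pos / mean_neg`.  Rule of thumb: a good HTS assay has
#' S/B above 3.  Unlike the standardized measures it ignores the spread
#' of both groups.
#'
#' @inheritParams z_prime
#' @export
sb_ratio <- function(cg) {
  cg <- as_control_groups(cg)
  mu_n <- mean(cg$neg)
  if (mu_n == 0)
    undefined_metric("sb_ratio", "negative-control mean is zero")
  mean(cg$pos) / mu_n
}

#' Signal-to-noise ratio
#'
#' `S/N = (mean_pos - mean_neg) / sd_neg`: the control separation in
#' units of the background fluctuation.
#'
#' @inheritParams z_prime
#' @export
sn_ratio <- function(cg) {
  cg <- as_control_groups(cg)
  check_group_sizes(cg, metric = "sn_ratio")
  sd_n <- stats::sd(cg$neg)
  if (sd_n == 0)
    undefined_metric("sn_ratio", "negative-control sd is zero")
  (mean(cg$pos) - mean(cg$neg)) / sd_n
}

#' Coefficient of variation
#'
#' `CV = sd / mean` (sample sd).  Dimensionless; non-negative whenever
#' all readouts are.
#'
#' @param values Numeric vector with at least two finite values and a
#'   non-zero mean.
#' @export
cv <- function(values) {
  s <- summarize_group(values)
  if (s$n < 2L)
    undefined_metric("cv", "need n >= 2 for a standard deviation")
  if (s$mean == 0)
    undefined_metric("cv", "mean is zero")
  s$sd / s$mean
}

#' Compute the full quality-metric panel for one assay
#'
#' Evaluates all eleven quality metrics -- Z'-factor, the three SSMD
#' estimators, Welch t (statistic, degrees of freedom and two-sided
#' p-value), the KS statistic, S/B, S/N and the per-group coefficients
#' of variation -- on one pair of control groups.  A metric that is
#' undefined on the data (zero denominator, too few replicates) is
#' carried as `NA` together with a reason string, never as a silent
#' zero, so a panel over many assays survives one degenerate plate.
#'
#' @inheritParams z_prime
#' @return An object of class `metric_panel`: a list with `metrics`
#'   (named numeric vector over the stable identifiers `z_prime`,
#'   `ssmd_mm`, `ssmd_mle`, `ssmd_robust`, `t_stat`, `t_pvalue`,
#'   `ks_stat`, `sb_ratio`, `sn_ratio`, `cv_pos`, `cv_neg`), `t_df`,
#'   `reasons` (named character vector for the `NA` entries), and the
#'   two `group_summary` objects.
#' @examples
#' metric_panel(control_groups(c(9, 10, 11), c(1, 2, 3)))
#' @export
metric_panel <- function(cg) {
  cg <- as_control_groups(cg)
  metrics <- stats::setNames(rep(NA_real_, length(METRIC_IDS)), METRIC_IDS)
  reasons <- character(0)
  t_df <- NA_real_

  grab <- function(id, expr) {
    tryCatch(expr, plateqc_undefined_metric = function(e) {
      reasons[[id]] <<- conditionMessage(e)
      NA_real_
    })
  }
  metrics[["z_prime"]]     <- grab("z_prime", z_prime(cg))
  metrics[["ssmd_mm"]]     <- grab("ssmd_mm", ssmd_mm(cg))
  metrics[["ssmd_mle"]]    <- grab("ssmd_mle", ssmd_mle(cg))
  metrics[["ssmd_robust"]] <- grab("ssmd_robust", ssmd_robust(cg))
  tt <- grab("t_stat", welch_t(cg))
  if (is.list(tt)) {
    metrics[["t_stat"]] <- tt$t
    metrics[["t_pvalue"]] <- tt$p
    t_df <- tt$df
  } else {
    reasons[["t_pvalue"]] <- reasons[["t_stat"]]
  }
  metrics[["ks_stat"]]  <- grab("ks_stat", ks_stat(cg$pos, cg$neg))
  metrics[["sb_ratio"]] <- grab("sb_ratio", sb_ratio(cg))
  metrics[["sn_ratio"]] <- grab("sn_ratio", sn_ratio(cg))
  metrics[["cv_pos"]]   <- grab("cv_pos", cv(cg$pos))
  metrics[["cv_neg"]]   <- grab("cv_neg", cv(cg$neg))

  structure(list(metrics = metrics, t_df = t_df, reasons = reasons,
                 pos = summarize_group(cg$pos),
                 neg = summarize_group(cg$neg)),
            class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, digits = 4, ...) {
  cat(sprintf("quality-metric panel (n_pos = %d, n_neg = %d)\n",
              x$pos$n, x$neg$n))
  vals <- format(signif(x$metrics, digits))
  vals[is.na(x$metrics)] <- "undefined"
  out <- data.frame(metric = names(x$metrics), value = vals,
                    row.names = NULL)
  print(out, right = FALSE, row.names = FALSE)
  if (length(x$reasons)) {
    cat("undefined metrics:\n")
    for (id in names(x$reasons))
      cat(sprintf("  %s: %s\n", id, x$reasons[[id]]))
  }
  invisible(x)
}

#' @export
as.data.frame.metric_panel <- function(x, ...) {
  data.frame(metric = names(x$metrics), value = unname(x$metrics),
             stringsAsFactors = FALSE)
}
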