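## Threshold classification of single assays and per-metric ranking of
## competing assays.

QUALITY_LABELS <- c("excellent", "good", "weak", "yes_no")

quality_call <- function(metric, label, basis, reason = NA_character_) {
  structure(list(metric = metric,
                 label = match.arg(label, QUALITY_LABELS),
                 basis = basis, reason = reason),
            class = "quality_call")
}

#' @export
print.quality_call <- function(x, ...) {
  cat(sprintf("%s = %s -> %s%s\n", x$metric,
              if (is.na(x$basis)) "undefined" else format(signif(x$basis, 4)),
              x$label,
              if (is.na(x$reason)) "" else paste0(" (", x$reason, ")")))
  invisible(x)
}

#' Classify an assay by its Z'-factor
#'
#' Thresholds follow the established Z'-factor bands: `[0.8, 1]` is an
#' excellent assay, `[0.5, 0.8)` a good one, `(0, 0.5)` a weak one, and
#' anything at or below 0 only supports a yes/no discrimination.  The
#' intervals are half-open so every value gets exactly one label.  An
#' undefined Z' (`NA`) is conservatively classified `yes_no`.
#'
#' @param z The Z'-factor, at most 1, or `NA` for an undefined metric.
#' @return A `quality_call` with label `excellent`, `good`, `weak` or
#'   `yes_no`.
#' @export
classify_z_prime <- function(z) {
  if (length(z) != 1L) input_error("'z' must be a single value")
  if (is.na(z))
    return(quality_call("z_prime", "yes_no", NA_real_,
                        reason = "metric undefined on the data"))
  if (!is.finite(z) || z > 1 + 1e-12)
    input_error("Z'-factor cannot exceed 1")
  label <- if (z >= 0.8) "excellent"
           else if (z >= 0.5) "good"
           else if (z > 0) "weak"
           else "yes_no"
  quality_call("z_prime", label, z)
}

#' Classify an assay by an SSMD estimate
#'
#' SSMD at or above 3 marks an excellent assay; anything smaller only
#' supports a yes/no discrimination.  Each SSMD variant is classified
#' independently.
#'
#' @param beta An SSMD estimate (any variant), or `NA`.
#' @param metric Identifier recorded in the call (default `"ssmd"`).
#' @export
classify_ssmd <- function(beta, metric = "ssmd") {
  if (length(beta) != 1L) input_error("'beta' must be a single value")
  if (is.na(beta))
    return(quality_call(metric, "yes_no", NA_real_,
                        reason = "metric undefined on the data"))
  if (!is.finite(beta)) input_error("'beta' must be finite")
  quality_call(metric, if (beta >= 3.0) "excellent" else "yes_no", beta)
}

#' Classify an assay by the Welch t-test decision
#'
#' Rejecting the null hypothesis of equal control means (two-sided
#' p-value below `alpha`) marks the assay excellent; failing to reject
#' leaves a yes/no assay.  The boundary `p == alpha` does not reject.
#'
#' @param p Two-sided p-value in `(0, 1]`, or `NA`.
#' @param alpha Significance level, default 0.05.
#' @export
classify_t <- function(p, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 0, strict = TRUE)
  if (alpha >= 1) input_error("'alpha' must be in (0, 1)")
  if (length(p) != 1L) input_error("'p' must be a single value")
  if (is.na(p))
    return(quality_call("t_pvalue", "yes_no", NA_real_,
                        reason = "metric undefined on the data"))
  if (!is.finite(p) || p <= 0 || p > 1)
    input_error("'p' must lie in (0, 1]")
  quality_call("t_pvalue", if (p < alpha) "excellent" else "yes_no", p,
               reason = if (p < alpha) "null hypothesis rejected"
                        else "null hypothesis accepted")
}

#' Classify every thresholded metric of a panel
#'
#' Applies the Z'-factor bands, the SSMD >= 3 rule (to each SSMD
#' variant independently) and the Welch-t decision to one
#' [metric_panel()].
#'
#' @param panel A `metric_panel`.
#' @param alpha Significance level for the t decision.
#' @return Named list of `quality_call` objects (`z_prime`, `ssmd_mm`,
#'   `ssmd_mle`, `ssmd_robust`, `t_pvalue`).
#' @export
classify_panel <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "metric_panel"))
  m <- panel$metrics
  list(
    z_prime = classify_z_prime(m[["z_prime"]]),
    ssmd_mm = classify_ssmd(m[["ssmd_mm"]], "ssmd_mm"),
    ssmd_mle = classify_ssmd(m[["ssmd_mle"]], "ssmd_mle"),
    ssmd_robust = classify_ssmd(m[["ssmd_robust"]], "ssmd_robust"),
    t_pvalue = classify_t(m[["t_pvalue"]], alpha = alpha)
  )
}

#' Rank assays per metric
#'
#' Builds the best-to-worst ranking matrix across assays, one column
#' per metric.  Rank 1 is best: the largest value for metrics where
#' separation is good (Z', SSMDs, t, KS, S/B, S/N) and the smallest for
#' those where small is good (p-value, CVs).  Ties share the minimum
#' rank; undefined (`NA`) metrics always rank last.
#'
#' @param panels Named list of `metric_panel` objects, one per assay
#'   (at least two).
#' @return An object of class `ranking_matrix`: an integer matrix with
#'   one row per assay and one column per metric, plus the underlying
#'   values as attribute `"values"`.
#' @export
rank_assays <- function(panels) {
  if (!length(panels)) input_error("no panels to rank")
  if (!all(vapply(panels, inherits, logical(1), "metric_panel")))
    input_error("'panels' must be a list of metric_panel objects")
  if (length(panels) < 2L)
    input_error("ranking needs at least two assays")
  ids <- names(panels)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == ""))
    input_error("'panels' must have unique non-empty names (assay ids)")

  values <- t(vapply(panels, function(p) p$metrics,
                     numeric(length(METRIC_IDS))))
  dimnames(values) <- list(ids, METRIC_IDS)
  ranks <- values
  for (metric in METRIC_IDS) {
    v <- values[, metric]
    key <- -METRIC_DIRECTIONS[[metric]] * v  # smaller key = better
    key[is.na(v)] <- Inf                     # undefined ranks last
    ranks[, metric] <- rank(key, ties.method = "min")
  }
  storage.mode(ranks) <- "integer"
  structure(ranks, class = c("ranking_matrix", class(ranks)),
            values = values)
}

#' @export
print.ranking_matrix <- function(x, ...) {
  cat("assay ranking per metric (1 = best; ties share the minimum rank)\n")
  print(unclass(structure(x, values = NULL)))
  invisible(x)
}

#' Heatmap of an assay ranking matrix
#'
#' Renders the ranking matrix with the conventional green (best) to red
#' (worst) palette.
#'
#' @param x A `ranking_matrix`.
#' @param ... Ignored.
#' @export
plot.ranking_matrix <- function(x, ...) {
  m <- unclass(structure(x, values = NULL))
  n <- max(m)
  pal <- grDevices::colorRampPalette(c("forestgreen", "gold", "firebrick"))(n)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "assay ranking (green = best)")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 1)
  invisible(x)
}

#' Evaluate a set of assay plates end to end
#'
#' The full evaluation pipeline: extract the control groups from each
#' endpoint plate, compute the quality-metric panel, classify the
#' thresholded metrics, and (for two or more assays) rank the assays
#' per metric.  Failures in any stage are annotated with the assay id.
#'
#' @param plates List of endpoint `plate_assay` objects (or a single
#'   one).  Assay ids must be unique.
#' @param alpha Significance level for the t-test classification.
#' @return An object of class `assay_report` with components `panels`,
#'   `calls` (both named by assay id) and `ranking` (a
#'   `ranking_matrix`, or `NULL` for a single assay).
#' @export
evaluate_assays <- function(plates, alpha = 0.05) {
  if (inherits(plates, "plate_assay")) plates <- list(plates)
  if (!length(plates)) input_error("no plates to evaluate")
  if (!all(vapply(plates, inherits, logical(1), "plate_assay")))
    input_error("'plates' must be plate_assay objects")
  ids <- vapply(plates, function(p) p$assay_id, character(1))
  if (anyDuplicated(ids))
    input_error(sprintf("duplicate assay id '%s'", ids[duplicated(ids)][1]))

  panels <- vector("list", length(plates))
  names(panels) <- ids
  for (i in seq_along(plates)) {
    panels[[i]] <- tryCatch(
      metric_panel(extract_controls(plates[[i]])),
      plateqc_error = function(e)
        qc_stop(sprintf("assay '%s': %s", ids[i], conditionMessage(e)),
                class(e)[1]))
  }
  calls <- lapply(panels, classify_panel, alpha = alpha)
  ranking <- if (length(panels) >= 2L) rank_assays(panels) else NULL
  structure(list(panels = panels, calls = calls, ranking = ranking,
                 alpha = alpha),
            class = "assay_report")
}

#' @export
print.assay_report <- function(x, ...) {
  cat(sprintf("assay evaluation report: %d assay(s), alpha = %g\n",
              length(x$panels), x$alpha))
  for (id in names(x$panels)) {
    cat("\n==", id, "==\n")
    print(x$panels[[id]])
    for (call in x$calls[[id]]) print(call)
  }
  if (!is.null(x$ranking)) {
    cat("\n")
    print(x$ranking)
  }
  invisible(x)
}

#' @export
summary.assay_report <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("assay evaluation report: %d assay(s)\n",
              length(object$panels)))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Flatten an assay report to one row per assay x metric
#'
#' @param x An `assay_report`.
#' @param ... Ignored.
#' @return Data frame with columns `assay`, `metric`, `value`, `rank`
#'   (NA for single-assay reports) and `classification` (NA for
#'   unthresholded metrics).
#' @export
as.data.frame.assay_report <- function(x, ...) {
  rows <- lapply(names(x$panels), function(id) {
    m <- x$panels[[id]]$metrics
    calls <- x$calls[[id]]
    labels <- vapply(METRIC_IDS, function(metric) {
      if (!is.null(calls[[metric]])) calls[[metric]]$label
      else NA_character_
    }, character(1))
    ranks <- if (!is.null(x$ranking)) x$ranking[id, METRIC_IDS]
             else rep(NA_integer_, length(METRIC_IDS))
    data.frame(assay = id, metric = METRIC_IDS, value = unname(m),
               rank = as.integer(unname(ranks)),
               classification = unname(labels),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
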