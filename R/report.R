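## Serialization of evaluation reports: nested JSON or a flat CSV,
## both reconstructible to the same assay x metric table.

#' Write an assay evaluation report
#'
#' Serializes an [evaluate_assays()] report either as nested JSON
#' (`assays -> {metrics, calls, rank}` plus the ranking matrix) or as
#' the equivalent flat CSV with one row per assay and metric.  Both
#' formats round-trip through [read_report()].
#'
#' @param report An `assay_report`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "assay_report"))
  if (!is.character(format) || !all(format %in% c("json", "csv")))
    input_error(sprintf("unknown report format '%s' (use json or csv)",
                        paste(format, collapse = ",")))
  format <- match.arg(format)
  flat <- as.data.frame(report)
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  assays <- lapply(names(report$panels), function(id) {
    sub <- flat[flat$assay == id, , drop = FALSE]
    metrics <- as.list(stats::setNames(sub$value, sub$metric))
    calls <- as.list(stats::setNames(sub$classification, sub$metric))
    calls <- calls[!is.na(unlist(calls))]
    rec <- list(metrics = metrics, calls = calls)
    if (!is.null(report$ranking))
      rec$rank <- as.list(stats::setNames(sub$rank, sub$metric))
    rec
  })
  names(assays) <- names(report$panels)
  payload <- list(assays = assays, alpha = report$alpha)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read back an assay evaluation report
#'
#' Reconstructs the flat assay x metric table written by
#' [write_report()], regardless of format.
#'
#' @param path Report file.
#' @param format `"json"` or `"csv"`.
#' @return Data frame with columns `assay`, `metric`, `value`, `rank`,
#'   `classification`.
#' @export
read_report <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  if (format == "csv") {
    out <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = "")
    out$value <- as.numeric(out$value)
    out$rank <- as.integer(out$rank)
    out$classification <- as.character(out$classification)
    return(out)
  }
  payload <- jsonlite::read_json(path)
  rows <- lapply(names(payload$assays), function(id) {
    rec <- payload$assays[[id]]
    metrics <- names(rec$metrics)
    value <- vapply(rec$metrics,
                    function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                    numeric(1))
    rank <- if (!is.null(rec$rank))
      vapply(rec$rank,
             function(v) if (is.null(v)) NA_integer_ else as.integer(v),
             integer(1))[metrics]
    else rep(NA_integer_, length(metrics))
    cls <- vapply(metrics, function(metric) {
      v <- rec$calls[[metric]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
    data.frame(assay = id, metric = metrics, value = unname(value),
               rank = as.integer(unname(rank)),
               classification = unname(cls), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
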