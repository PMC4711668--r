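## Classed error helpers so callers (and the CLI) can distinguish bad input
## from metrics that are mathematically undefined on the given data.

qc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "plateqc_error", "error"),
                      call = call))
}

input_error <- function(msg) qc_stop(msg, "plateqc_input_error")

undefined_metric <- function(metric, reason) {
  qc_stop(sprintf("metric '%s' is undefined: %s", metric, reason),
          "plateqc_undefined_metric")
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    input_error(sprintf("'%s' must be a single finite number", name))
  if (strict && x <= lower)
    input_error(sprintf("'%s' must be > %s", name, format(lower)))
  if (!strict && x < lower)
    input_error(sprintf("'%s' must be >= %s", name, format(lower)))
  as.numeric(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    input_error(sprintf("'%s' must be a single integer", name))
  if (x < lower)
    input_error(sprintf("'%s' must be >= %d", name, lower))
  as.integer(x)
}
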