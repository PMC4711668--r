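## Readout quantification: time-series summaries, linear calibration
## between absorbance and concentration, initial rates, specific
## activity and turnover numbers.
##
## Unit conventions (never converted implicitly): time in minutes,
## concentration in mM, volume in litres, enzyme mass in mg, molecular
## weight in kDa, specific activity in umol min^-1 mg^-1, turnover in
## s^-1.

#' Construct a measurement time series
#'
#' @param times Strictly increasing numeric vector, minutes.
#' @param values Numeric vector of the same length.
#' @return An object of class `time_series`.
#' @export
time_series <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (!length(times)) input_error("time series must hold at least one point")
  if (length(times) != length(values))
    input_error("'times' and 'values' must have the same length")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    input_error("time series entries must be finite")
  if (any(times < 0)) input_error("times must be >= 0 minutes")
  if (is.unsorted(times, strictly = TRUE))
    input_error("times must be strictly increasing")
  structure(list(times = times, values = values), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("time series: %d points over [%g, %g] min\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
plot.time_series <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "b", xlab = "time [min]",
                 ylab = "readout", ...)
  invisible(x)
}

as_time_series <- function(ts) {
  if (inherits(ts, "time_series")) return(ts)
  if (is.data.frame(ts) && all(c("time", "value") %in% names(ts)))
    return(time_series(ts$time, ts$value))
  input_error("expected a time_series object")
}

#' Mean of a time series
#'
#' Arithmetic mean of the readouts, one of the two endpoint summaries
#' used for slowly decaying luminescence signals.
#'
#' @param ts A [time_series()].
#' @export
series_mean <- function(ts) {
  ts <- as_time_series(ts)
  mean(ts$values)
}

#' Numeric integral of a time series
#'
#' Trapezoidal integral of the readout over `[t_first, t_last]` (units:
#' value x minutes).  The trapezoid rule is exact for the piecewise
#' linear traces a plate reader produces.
#'
#' @param ts A [time_series()] with at least two points.
#' @export
series_integral <- function(ts) {
  ts <- as_time_series(ts)
  if (length(ts$times) < 2L)
    input_error("integral needs at least two points (no duration otherwise)")
  dt <- diff(ts$times)
  v <- ts$values
  sum(dt * (v[-length(v)] + v[-1]) / 2)
}

#' Fit a linear calibration between concentration and absorbance
#'
#' Ordinary least squares of absorbance on concentration, as used to
#' turn pH-indicator absorbance into acid concentration (calibration
#' points are produced by spiking known HCl concentrations into the
#' assay buffer).  The Pearson correlation of the point set is reported
#' as the usual linearity diagnostic.
#'
#' @param concentration Concentrations in mM (or a data frame with
#'   columns `concentration_mM` and `absorbance`, in which case
#'   `absorbance` is ignored).
#' @param absorbance Absorbances in AU.
#' @return An object of class `calibration` with fields `slope` (AU per
#'   mM), `intercept` (AU), `pearson_r` and `n_points`.  Supports
#'   `coef()`, `predict()` (concentration -> absorbance),
#'   `residuals()`, `print()` and `plot()`.
#' @examples
#' cal <- fit_calibration(c(0, 1, 2), c(0.9, 0.6, 0.3))
#' coef(cal)                     # intercept 0.9, slope -0.3
#' invert_calibration(cal, 0.45) # 1.5 mM
#' @export
fit_calibration <- function(concentration, absorbance = NULL) {
  if (is.data.frame(concentration)) {
    df <- concentration
    if (!all(c("concentration_mM", "absorbance") %in% names(df)))
      input_error("calibration table needs columns concentration_mM, absorbance")
    concentration <- df$concentration_mM
    absorbance <- df$absorbance
  }
  concentration <- as.numeric(concentration)
  absorbance <- as.numeric(absorbance)
  if (length(concentration) != length(absorbance))
    input_error("'concentration' and 'absorbance' must have the same length")
  if (length(concentration) < 2L)
    input_error("calibration needs at least two points")
  if (any(!is.finite(concentration)) || any(!is.finite(absorbance)))
    input_error("calibration points must be finite")
  if (length(unique(concentration)) < 2L)
    input_error("degenerate calibration: all concentrations are equal")

  fit <- stats::lm(absorbance ~ concentration)
  r <- if (stats::sd(absorbance) == 0) {
    ## flat line: correlation undefined, but the fit is exact
    0
  } else {
    stats::cor(concentration, absorbance)
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r,
                 n_points = length(concentration),
                 residuals = unname(stats::residuals(fit)),
                 data = data.frame(concentration_mM = concentration,
                                   absorbance = absorbance)),
            class = "calibration")
}

#' @export
coef.calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.calibration <- function(object, ...) object$residuals

#' Predict absorbance from concentration
#'
#' @param object A `calibration`.
#' @param concentration Concentrations in mM.
#' @param ... Ignored.
#' @return Predicted absorbances (AU).
#' @export
predict.calibration <- function(object, concentration, ...) {
  object$intercept + object$slope * as.numeric(concentration)
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "linear calibration: absorbance = %.6g %+.6g * conc_mM (r = %.4f, n = %d)\n",
    x$intercept, x$slope, x$pearson_r, x$n_points))
  invisible(x)
}

#' @export
plot.calibration <- function(x, ...) {
  graphics::plot(x$data$concentration_mM, x$data$absorbance,
                 xlab = "concentration [mM]", ylab = "absorbance [AU]",
                 main = sprintf("calibration (r = %.4f)", x$pearson_r), ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  invisible(x)
}

#' Invert a calibration: absorbance to concentration
#'
#' `(absorbance - intercept) / slope`; the inverse of
#' [predict.calibration()].
#'
#' @param model A `calibration` with non-zero slope.
#' @param absorbance Absorbances in AU.
#' @return Concentrations in mM.
#' @export
invert_calibration <- function(model, absorbance) {
  stopifnot(inherits(model, "calibration"))
  ## a fitted slope is never an exact 0 in floating point; treat
  ## anything at rounding-error scale relative to the intercept as flat
  if (abs(model$slope) <= 1e-12 * max(1, abs(model$intercept)))
    input_error("cannot invert a calibration with zero slope")
  (as.numeric(absorbance) - model$intercept) / model$slope
}

#' Read calibration points from CSV
#'
#' Expects the header `concentration_mM,absorbance`.
#'
#' @param path CSV path.
#' @return Data frame suitable for [fit_calibration()].
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration_mM", "absorbance") %in% names(df)))
    input_error(sprintf("%s must have columns concentration_mM, absorbance",
                        path))
  df
}

#' Initial rate of a progress curve
#'
#' Least-squares slope of concentration against time over an initial
#' window of the series, the standard initial-rate estimate for an
#' enzymatic reaction.  The window defaults to the first 5 points or
#' the first 10% of the series, whichever is larger; the fit's r-squared
#' is attached so curved windows can be rejected by the caller.
#'
#' @param conc_series A [time_series()] of concentrations (mM) over
#'   minutes.
#' @param window Number of leading points (integer >= 3) or a fraction
#'   in (0, 1) of the series length; `NULL` for the default rule.
#' @return An object of class `rate_fit` with fields `rate` (mM/min),
#'   `r_squared` and `n_window`.
#' @examples
#' ts <- time_series(0:5, 0.1 * (0:5))
#' initial_rate(ts)$rate  # 0.1
#' @export
initial_rate <- function(conc_series, window = NULL) {
  ts <- as_time_series(conc_series)
  n <- length(ts$times)
  k <- if (is.null(window)) {
    max(5L, ceiling(0.1 * n))
  } else if (length(window) == 1L && is.numeric(window) && is.finite(window)
             && window > 0 && window < 1) {
    ceiling(window * n)
  } else {
    check_count(window, "window", lower = 3L)
  }
  k <- min(k, n)
  if (k > n) input_error("window exceeds the series length")
  if (k < 3L || n < 3L)
    input_error("initial-rate fit needs at least 3 points in the window")
  t0 <- ts$times[seq_len(k)]
  c0 <- ts$values[seq_len(k)]
  fit <- stats::lm(c0 ~ t0)
  ss_tot <- sum((c0 - mean(c0))^2)
  r2 <- if (ss_tot == 0) 1
        else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(rate = unname(stats::coef(fit)[2]),
                 r_squared = r2, n_window = k),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("initial rate: %.6g mM/min (r^2 = %.4f over %d points)\n",
              x$rate, x$r_squared, x$n_window))
  invisible(x)
}

#' Specific activity from an initial rate
#'
#' `rate [mM/min] x volume [L] / mass [mg]`, expressed in
#' umol min^-1 mg^-1 (1 mM x 1 L = 1 mmol = 1000 umol).
#'
#' @param rate Initial rate in mM/min.
#' @param volume_L Reaction volume in litres (e.g. 200 uL = 2e-4).
#' @param enzyme_mass_mg Enzyme mass in the well, mg.
#' @return Specific activity in umol min^-1 mg^-1.
#' @examples
#' specific_activity(0.1, 200e-6, 0.01)  # 2
#' @export
specific_activity <- function(rate, volume_L, enzyme_mass_mg) {
  rate <- check_number(rate, "rate")
  volume_L <- check_number(volume_L, "volume_L", lower = 0, strict = TRUE)
  enzyme_mass_mg <- check_number(enzyme_mass_mg, "enzyme_mass_mg",
                                 lower = 0, strict = TRUE)
  rate * volume_L * 1000 / enzyme_mass_mg
}

#' Turnover number from specific activity
#'
#' Converts a specific activity to the per-active-site turnover number.
#' Per mg of enzyme the product flux is `sa x 1e-6 mol/min`, and one mg
#' holds `1e-3 / (mw [g/mol])` mol of molecules, so
#' `kcat [s^-1] = sa x 1e-6 x (mw x 1000) x 1000 / (60 x sites)
#'             = sa x mw_kDa / (60 x sites)`.
#' One active site per monomer is the default (one catalytic triad per
#' lipase or esterase chain); doubling the site count halves the
#' turnover.
#'
#' @param sa Specific activity, umol min^-1 mg^-1.
#' @param mw_kDa Molecular weight of the enzyme, kDa.
#' @param sites_per_molecule Active sites per molecule (default 1).
#' @return Turnover number in s^-1.
#' @examples
#' turnover_number(2, 29)  # 0.9667 for a 29 kDa lipase
#' @export
turnover_number <- function(sa, mw_kDa, sites_per_molecule = 1L) {
  sa <- check_number(sa, "sa")
  mw_kDa <- check_number(mw_kDa, "mw_kDa", lower = 0, strict = TRUE)
  sites_per_molecule <- check_count(sites_per_molecule,
                                    "sites_per_molecule", lower = 1L)
  sa * mw_kDa / (60 * sites_per_molecule)
}

#' Quantify enzymatic activity from an absorbance trace
#'
#' The full quantification chain for one well: optional blank
#' subtraction, inversion of the calibration to concentrations, the
#' initial-rate fit, specific activity and turnover number.
#'
#' @param absorbance_series A [time_series()] of absorbances (AU).
#' @param calibration A [fit_calibration()] model.
#' @param volume_L Reaction volume in litres.
#' @param enzyme_mass_mg Enzyme mass per well, mg.
#' @param mw_kDa Enzyme molecular weight, kDa.
#' @param sites_per_molecule Active sites per molecule.
#' @param window Initial-rate window, see [initial_rate()].
#' @param blank Optional blank absorbance (AU) subtracted from the
#'   trace before inversion.
#' @return An object of class `activity_result` with fields
#'   `initial_rate` (mM/min), `r_squared`, `specific_activity`
#'   (umol min^-1 mg^-1) and `turnover` (s^-1).
#' @export
quantify_activity <- function(absorbance_series, calibration, volume_L,
                              enzyme_mass_mg, mw_kDa,
                              sites_per_molecule = 1L, window = NULL,
                              blank = NULL) {
  ts <- as_time_series(absorbance_series)
  stopifnot(inherits(calibration, "calibration"))
  values <- ts$values
  if (!is.null(blank)) values <- values - check_number(blank, "blank")
  conc <- invert_calibration(calibration, values)
  rate <- initial_rate(time_series(ts$times, conc), window = window)
  sa <- specific_activity(rate$rate, volume_L, enzyme_mass_mg)
  structure(list(initial_rate = rate$rate,
                 r_squared = rate$r_squared,
                 specific_activity = sa,
                 turnover = turnover_number(sa, mw_kDa,
                                            sites_per_molecule)),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf(
    "initial rate %.4g mM/min (r^2 %.4f); specific activity %.4g umol/min/mg; turnover %.4g 1/s\n",
    x$initial_rate, x$r_squared, x$specific_activity, x$turnover))
  invisible(x)
}
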