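## Synthetic control plates, luminescence traces and progress curves.
##
## The control model is Gaussian per group -- the 3-sigma reasoning
## behind the Z'-factor presumes approximate normality -- with an
## optional scale-mixture contamination (a fraction of wells redrawn at
## an inflated sigma) as the simplest outlier mechanism that separates
## the robust SSMD from the moment-based ones.  One integer seed per
## spec makes every draw bit-reproducible; per-group sub-streams are
## derived from it deterministically.

#' Specification of a simulated control experiment
#'
#' Defaults emulate a half-plate evaluation run: 46 positive and 46
#' negative wells (the midpoint of the 44-48 replicates typical of a
#' 96-well half-plate design), normally distributed readouts, no
#' contamination.
#'
#' @param mu_pos,sd_pos Mean and sd of the positive-control readout.
#' @param mu_neg,sd_neg Mean and sd of the negative-control readout.
#' @param n_pos,n_neg Replicates per group (>= 2).
#' @param outlier_frac Fraction of each group redrawn as outliers, in
#'   `[0, 0.5)`.
#' @param outlier_scale Sigma inflation of the outlier draws (>= 1).
#' @param seed Integer seed; same spec + seed gives identical output.
#' @return An object of class `control_spec`.
#' @export
control_spec <- function(mu_pos = 1.0, sd_pos = 0.05,
                         mu_neg = 0.1, sd_neg = 0.05,
                         n_pos = 46L, n_neg = 46L,
                         outlier_frac = 0, outlier_scale = 1,
                         seed = 1L) {
  spec <- list(
    mu_pos = check_number(mu_pos, "mu_pos"),
    sd_pos = check_number(sd_pos, "sd_pos", lower = 0),
    mu_neg = check_number(mu_neg, "mu_neg"),
    sd_neg = check_number(sd_neg, "sd_neg", lower = 0),
    n_pos = check_count(n_pos, "n_pos", lower = 2L),
    n_neg = check_count(n_neg, "n_neg", lower = 2L),
    outlier_frac = check_number(outlier_frac, "outlier_frac", lower = 0),
    outlier_scale = check_number(outlier_scale, "outlier_scale", lower = 1),
    seed = check_count(seed, "seed", lower = 0L)
  )
  if (spec$outlier_frac >= 0.5)
    input_error("'outlier_frac' must be < 0.5")
  structure(spec, class = "control_spec")
}

#' @export
print.control_spec <- function(x, ...) {
  cat(sprintf(
    "control spec: pos N(%g, %g) x %d, neg N(%g, %g) x %d, outliers %g%% at %gx sigma, seed %d\n",
    x$mu_pos, x$sd_pos, x$n_pos, x$mu_neg, x$sd_neg, x$n_neg,
    100 * x$outlier_frac, x$outlier_scale, x$seed))
  invisible(x)
}

## Draw one contaminated Gaussian group under its own RNG sub-stream.
draw_group <- function(n, mu, sd, frac, scale, seed) {
  set.seed(seed %% .Machine$integer.max)
  x <- stats::rnorm(n, mu, sd)
  n_out <- round(frac * n)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    x[idx] <- stats::rnorm(n_out, mu, scale * sd)
  }
  x
}

#' Simulate paired control groups
#'
#' Each group is drawn from its Normal distribution; a fraction
#' `outlier_frac` of the points (rounded to a count) is replaced by
#' draws at `outlier_scale` times the group sigma.
#'
#' @param spec A [control_spec()].
#' @return A [control_groups()] object.
#' @examples
#' cg <- simulate_controls(control_spec(seed = 7))
#' z_prime(cg)
#' @export
simulate_controls <- function(spec) {
  stopifnot(inherits(spec, "control_spec"))
  pos <- draw_group(spec$n_pos, spec$mu_pos, spec$sd_pos,
                    spec$outlier_frac, spec$outlier_scale,
                    seed = 2 * spec$seed)
  neg <- draw_group(spec$n_neg, spec$mu_neg, spec$sd_neg,
                    spec$outlier_frac, spec$outlier_scale,
                    seed = 2 * spec$seed + 1)
  control_groups(pos, neg)
}

#' Simulate a half-plate control experiment as a plate
#'
#' Lays the simulated readouts out on a 96-well endpoint plate:
#' positives occupy the first `n_pos` wells in row-major order
#' (A1, A2, ...), negatives the following `n_neg`, mirroring the
#' half-positive / half-negative evaluation design.
#' [extract_controls()] inverts this exactly.
#'
#' @param spec A [control_spec()] with `n_pos + n_neg <= 96`.
#' @param assay_id Plate identifier.
#' @param detection Detection mode recorded on the plate.
#' @return An endpoint `plate_assay`.
#' @export
simulate_control_plate <- function(spec, assay_id = "simulated",
                                   detection = "absorbance") {
  stopifnot(inherits(spec, "control_spec"))
  if (spec$n_pos + spec$n_neg > 96L)
    input_error(sprintf(
      "n_pos + n_neg = %d exceeds the 96-well plate capacity",
      spec$n_pos + spec$n_neg))
  cg <- simulate_controls(spec)
  wells <- well_labels()[seq_len(spec$n_pos + spec$n_neg)]
  plate_assay(data.frame(
    well = wells,
    role = rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg)),
    value = c(cg$pos, cg$neg)
  ), assay_id = assay_id, detection = detection)
}

#' Simulate a decaying luminescence trace
#'
#' Single-exponential decay `peak * exp(-t / tau)` sampled on a regular
#' grid, plus additive Gaussian noise.  The noiseless trapezoidal
#' integral approaches `peak * tau * (1 - exp(-duration / tau))`.
#'
#' @param peak Signal at time zero (counts).
#' @param tau_min Decay time constant, minutes.
#' @param duration_min Total measurement window, minutes.
#' @param dt_min Sampling interval, minutes.
#' @param noise_sd Additive noise sd (counts).
#' @param seed Integer seed.
#' @return A [time_series()].
#' @export
simulate_luminescence <- function(peak, tau_min, duration_min, dt_min,
                                  noise_sd = 0, seed = 1L) {
  peak <- check_number(peak, "peak")
  tau_min <- check_number(tau_min, "tau_min", lower = 0, strict = TRUE)
  duration_min <- check_number(duration_min, "duration_min", lower = 0,
                               strict = TRUE)
  dt_min <- check_number(dt_min, "dt_min", lower = 0, strict = TRUE)
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0)
  seed <- check_count(seed, "seed", lower = 0L)
  times <- seq(0, duration_min, by = dt_min)
  set.seed(seed)
  values <- peak * exp(-times / tau_min) +
    stats::rnorm(length(times), 0, noise_sd)
  time_series(times, values)
}

#' Specification of a simulated enzymatic progress curve
#'
#' The product concentration follows `S0 * (1 - exp(-k t))` with `k`
#' chosen so the initial slope equals `rate_mM_per_min`; absorbance is
#' the calibration forward map of the concentration plus noise.
#' Defaults mirror the screening conditions: 2 mM substrate, a 30 min
#' run.
#'
#' @param rate_mM_per_min True initial rate, mM/min.
#' @param substrate_mM Substrate concentration S0, mM (default 2).
#' @param duration_min Run length, minutes (default 30).
#' @param dt_min Sampling interval, minutes (default 0.5).
#' @param noise_sd Additive absorbance noise sd (AU).
#' @param calibration A [fit_calibration()] model mapping mM to AU.
#' @param seed Integer seed.
#' @return An object of class `kinetic_spec`.
#' @export
kinetic_spec <- function(rate_mM_per_min, substrate_mM = 2.0,
                         duration_min = 30, dt_min = 0.5,
                         noise_sd = 0, calibration, seed = 1L) {
  stopifnot(inherits(calibration, "calibration"))
  structure(list(
    rate_mM_per_min = check_number(rate_mM_per_min, "rate_mM_per_min",
                                   lower = 0),
    substrate_mM = check_number(substrate_mM, "substrate_mM", lower = 0,
                                strict = TRUE),
    duration_min = check_number(duration_min, "duration_min", lower = 0,
                                strict = TRUE),
    dt_min = check_number(dt_min, "dt_min", lower = 0, strict = TRUE),
    noise_sd = check_number(noise_sd, "noise_sd", lower = 0),
    calibration = calibration,
    seed = check_count(seed, "seed", lower = 0L)
  ), class = "kinetic_spec")
}

#' Simulate an enzymatic progress curve
#'
#' @param spec A [kinetic_spec()].
#' @return A list with two [time_series()]: `conc` (mM, noiseless) and
#'   `absorbance` (AU, calibration forward map of `conc` plus noise).
#' @examples
#' cal <- fit_calibration(c(0, 1, 2), c(0.9, 0.6, 0.3))
#' sim <- simulate_progress_curve(kinetic_spec(0.1, calibration = cal))
#' initial_rate(sim$conc)$rate
#' @export
simulate_progress_curve <- function(spec) {
  stopifnot(inherits(spec, "kinetic_spec"))
  times <- seq(0, spec$duration_min, by = spec$dt_min)
  k <- spec$rate_mM_per_min / spec$substrate_mM
  conc <- spec$substrate_mM * (1 - exp(-k * times))
  set.seed(spec$seed)
  absorbance <- predict(spec$calibration, conc) +
    stats::rnorm(length(times), 0, spec$noise_sd)
  list(conc = time_series(times, conc),
       absorbance = time_series(times, absorbance))
}

#' Read a control spec from a YAML or JSON config file
#'
#' Keys are the [control_spec()] arguments; missing keys take the
#' defaults.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A `control_spec`.
#' @export
read_control_spec <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) input_error(sprintf("config %s is not a mapping", path))
  allowed <- names(formals(control_spec))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    input_error(sprintf("unknown control-spec key '%s' in %s", bad[1], path))
  do.call(control_spec, cfg)
}
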