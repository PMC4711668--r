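test_that("control simulation is seed-deterministic with the right sizes", {
  spec <- control_spec(n_pos = 44, n_neg = 48, seed = 9)
  cg1 <- simulate_controls(spec)
  cg2 <- simulate_controls(spec)
  expect_identical(cg1$pos, cg2$pos)
  expect_identical(cg1$neg, cg2$neg)
  expect_length(cg1$pos, 44L)
  expect_length(cg1$neg, 48L)

  # different seed, different draws
  cg3 <- simulate_controls(control_spec(n_pos = 44, n_neg = 48, seed = 10))
  expect_false(identical(cg1$pos, cg3$pos))

  # per-group sub-streams: the positive draws do not depend on n_neg
  cg4 <- simulate_controls(control_spec(n_pos = 44, n_neg = 20, seed = 9))
  expect_identical(cg4$pos, cg1$pos)
})

test_that("large samples match the requested moments", {
  cg <- simulate_controls(control_spec(mu_pos = 0, sd_pos = 1,
                                       mu_neg = 5, sd_neg = 2,
                                       n_pos = 1e5, n_neg = 1e5,
                                       seed = 3))
  expect_lt(abs(mean(cg$pos)), 4 / sqrt(1e5))
  expect_equal(sd(cg$pos), 1, tolerance = 0.02)
  expect_equal(mean(cg$neg), 5, tolerance = 0.01)
})

test_that("spec validation rejects impossible parameters", {
  expect_error(control_spec(n_pos = 1), "n_pos")
  expect_error(control_spec(sd_pos = -1), "sd_pos")
  expect_error(control_spec(outlier_frac = 0.6), "outlier_frac")
  expect_error(control_spec(outlier_scale = 0.5), "outlier_scale")
})

test_that("simulated plates lay controls half-and-half in row-major order", {
  spec <- control_spec(n_pos = 48, n_neg = 48, seed = 21)
  plate <- simulate_control_plate(spec)
  expect_true(is_endpoint(plate))
  expect_equal(sum(plate$data$role == "positive"), 48L)
  # positives fill rows A-D (wells A1..D12), negatives E-H
  expect_equal(plate$data$well[plate$data$role == "positive"],
               well_labels()[1:48])

  # extraction inverts simulation exactly
  cg <- simulate_controls(spec)
  back <- extract_controls(plate)
  expect_identical(back$pos, cg$pos)
  expect_identical(back$neg, cg$neg)

  expect_error(simulate_control_plate(control_spec(n_pos = 50, n_neg = 50)),
               "capacity")
})

test_that("luminescence decay matches its closed-form integral", {
  ts <- simulate_luminescence(peak = 100, tau_min = 10, duration_min = 50,
                              dt_min = 0.5, noise_sd = 0)
  expect_equal(series_integral(ts), 100 * 10 * (1 - exp(-5)),
               tolerance = 0.01)
  expect_equal(ts$values[1], 100)

  zero <- simulate_luminescence(peak = 0, tau_min = 10, duration_min = 10,
                                dt_min = 1, noise_sd = 0)
  expect_true(all(zero$values == 0))

  n1 <- simulate_luminescence(100, 10, 50, 0.5, noise_sd = 5, seed = 4)
  n2 <- simulate_luminescence(100, 10, 50, 0.5, noise_sd = 5, seed = 4)
  expect_identical(n1$values, n2$values)
  expect_error(simulate_luminescence(100, -1, 50, 0.5), "tau")
})

test_that("progress curves carry the requested initial rate", {
  cal <- fit_calibration(c(0, 1, 2), c(0.9, 0.6, 0.3))
  sim <- simulate_progress_curve(kinetic_spec(0.1, dt_min = 0.1,
                                              calibration = cal))
  est <- initial_rate(sim$conc, window = 3)$rate
  expect_equal(est, 0.1, tolerance = 0.05)
  # absorbance is the calibration forward map of the concentration
  expect_equal(sim$absorbance$values, predict(cal, sim$conc$values))

  flat <- simulate_progress_curve(kinetic_spec(0, calibration = cal))
  expect_true(all(flat$conc$values == 0))
  expect_true(all(flat$absorbance$values == cal$intercept))

  noisy1 <- simulate_progress_curve(kinetic_spec(0.1, noise_sd = 0.01,
                                                 calibration = cal,
                                                 seed = 8))
  noisy2 <- simulate_progress_curve(kinetic_spec(0.1, noise_sd = 0.01,
                                                 calibration = cal,
                                                 seed = 8))
  expect_identical(noisy1$absorbance$values, noisy2$absorbance$values)
})

test_that("sampled Z' concentrates on the population value", {
  # population Z' = 1 - 3(sd_pos + sd_neg)/|mu_diff|: 0 at 6-sigma
  # separation, 0.5 at 12-sigma
  for (setting in list(c(delta = 6, z = 0), c(delta = 12, z = 0.5))) {
    zs <- vapply(1:500, function(rep) {
      z_prime(simulate_controls(control_spec(
        mu_pos = setting[["delta"]], sd_pos = 1, mu_neg = 0, sd_neg = 1,
        seed = 7000 + rep)))
    }, numeric(1))
    expect_equal(mean(zs), setting[["z"]], tolerance = 0.05)
  }
})

test_that("contamination moves the MM estimator more than the robust one", {
  n_rep <- 100L
  d_mm <- d_rob <- numeric(n_rep)
  for (rep in seq_len(n_rep)) {
    base <- control_spec(mu_pos = 6, sd_pos = 1, mu_neg = 0, sd_neg = 1,
                         seed = 5000 + rep)
    dirty <- control_spec(mu_pos = 6, sd_pos = 1, mu_neg = 0, sd_neg = 1,
                          outlier_frac = 0.05, outlier_scale = 20,
                          seed = 5000 + rep)
    clean_cg <- simulate_controls(base)
    dirty_cg <- simulate_controls(dirty)
    d_mm[rep] <- abs(ssmd_mm(dirty_cg) - ssmd_mm(clean_cg))
    d_rob[rep] <- abs(ssmd_robust(dirty_cg) - ssmd_robust(clean_cg))
  }
  expect_lt(median(d_rob), median(d_mm))
})

test_that("control specs load from YAML and JSON configs", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mu_pos: 2.5", "n_pos: 44", "seed: 12"), yml)
  spec <- read_control_spec(yml)
  expect_s3_class(spec, "control_spec")
  expect_equal(spec$mu_pos, 2.5)
  expect_equal(spec$n_pos, 44L)
  expect_equal(spec$sd_pos, 0.05)  # defaults fill the gaps

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"mu_neg": 0.2, "seed": 3}', js)
  spec2 <- read_control_spec(js)
  expect_equal(spec2$mu_neg, 0.2)

  writeLines("wrong_key: 1", yml)
  expect_error(read_control_spec(yml), "wrong_key")
})
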