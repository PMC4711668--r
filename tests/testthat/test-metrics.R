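test_that("group summaries use sample sd and the scaled MAD", {
  s <- summarize_group(c(1, 2, 3))
  expect_equal(s$n, 3L)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$median, 2)
  expect_equal(s$mad, 1.4826)   # 1.4826 * median(|x - 2|) = 1.4826 * 1

  const <- summarize_group(rep(5, 4))
  expect_equal(const$sd, 0)
  expect_equal(const$mad, 0)

  one <- summarize_group(7)
  expect_true(is.na(one$sd))    # sd undefined at n = 1, flagged not 0

  expect_error(summarize_group(numeric(0)), "empty")
  expect_error(summarize_group(c(1, NA)), "finite")
})

test_that("Z'-factor matches its hand-evaluated form and edge cases", {
  expect_equal(z_prime(fixture_cg()), 1 - 3 * (1 + 1) / 8)  # 0.25
  expect_equal(z_prime(control_groups(c(4, 4, 4), c(1, 1, 1))), 1)
  expect_error(z_prime(control_groups(c(1, 2, 3), c(1, 2, 3))),
               class = "plateqc_undefined_metric")
})

test_that("the three SSMD estimators match hand evaluation", {
  cg <- fixture_cg()
  expect_equal(ssmd_mm(cg), 8 / sqrt(2))
  expect_equal(ssmd_mle(cg), 8 / sqrt(2 / 3 + 2 / 3))
  expect_equal(ssmd_robust(cg), 8 / (1.4826 * sqrt(2)))

  ident <- control_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ssmd_mm(ident), 0)
  expect_equal(ssmd_mle(ident), 0)
  expect_equal(ssmd_robust(ident), 0)

  expect_error(ssmd_mm(control_groups(c(4, 4), c(1, 1))),
               class = "plateqc_undefined_metric")
  expect_error(ssmd_robust(control_groups(c(4, 4), c(1, 1))),
               class = "plateqc_undefined_metric")
})

test_that("MLE variant dominates MM and converges to it for large n", {
  cg <- fixture_cg()
  expect_true(abs(ssmd_mle(cg)) >= abs(ssmd_mm(cg)))
  # the ratio is sqrt(n/(n-1)) at equal group sizes, so it vanishes
  set.seed(42)
  big <- control_groups(rnorm(20000, 5), rnorm(20000, 0))
  expect_equal(ssmd_mle(big), ssmd_mm(big), tolerance = 1e-4)
})

test_that("the robust SSMD resists an outlier that collapses the MM variant", {
  neg <- c(1, 2, 3)
  clean <- control_groups(c(9, 10, 11, 12), neg)
  dirty <- control_groups(c(9, 10, 11, 1000), neg)
  rel_robust <- abs(ssmd_robust(dirty) - ssmd_robust(clean)) /
    abs(ssmd_robust(clean))
  expect_lt(rel_robust, 0.20)
  expect_lt(abs(ssmd_mm(dirty)), 0.2 * abs(ssmd_mm(clean)))
})

test_that("Welch t matches the hand formula and is antisymmetric", {
  cg <- fixture_cg()
  res <- welch_t(cg)
  expect_equal(res$t, 8 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_lt(res$p, 0.001)

  ident <- welch_t(control_groups(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  swapped <- welch_t(control_groups(cg$neg, cg$pos))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$df, res$df)
  expect_equal(swapped$p, res$p)
})

test_that("KS statistic handles the canonical cases", {
  expect_equal(ks_stat(c(1, 2, 3), c(10, 11, 12)), 1)
  expect_equal(ks_stat(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_stat(c(1, 3), c(2, 4)), 0.5)
  expect_error(ks_stat(numeric(0), 1), "non-empty")
})

test_that("KS statistic agrees with brute force and stats::ks.test", {
  set.seed(101)
  for (i in 1:200) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    a <- round(rnorm(n1), 1)  # rounding forces ties within and across
    b <- round(rnorm(n2, sample(c(0, 1), 1)), 1)
    d <- ks_stat(a, b)
    expect_equal(d, ks_brute(a, b), tolerance = 1e-12)
    expect_equal(d,
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("KS statistic is invariant under strictly increasing transforms", {
  set.seed(7)
  a <- rnorm(20); b <- rnorm(15, 1)
  d <- ks_stat(a, b)
  expect_equal(ks_stat(exp(a), exp(b)), d)
  expect_equal(ks_stat(a^3, b^3), d)
})

test_that("S/B, S/N and CV match hand evaluation with classed errors", {
  cg <- fixture_cg()
  expect_equal(sb_ratio(cg), 5)
  expect_equal(sn_ratio(cg), 8)
  expect_equal(cv(c(9, 10, 11)), 0.1)
  expect_equal(cv(c(10, 10, 10)), 0)

  expect_error(sb_ratio(control_groups(c(1, 2), c(-1, 1))),
               class = "plateqc_undefined_metric")
  expect_error(sn_ratio(control_groups(c(1, 2), c(1, 1))),
               class = "plateqc_undefined_metric")
  expect_error(cv(c(-1, 1)), class = "plateqc_undefined_metric")
})

test_that("metric panel unions the individual metrics", {
  p <- metric_panel(fixture_cg())
  m <- p$metrics
  expect_equal(sort(names(m)),
               sort(c("z_prime", "ssmd_mm", "ssmd_mle", "ssmd_robust",
                      "t_stat", "t_pvalue", "ks_stat", "sb_ratio",
                      "sn_ratio", "cv_pos", "cv_neg")))
  expect_equal(m[["z_prime"]], 0.25)
  expect_equal(m[["ssmd_mm"]], 8 / sqrt(2))
  expect_equal(m[["ks_stat"]], 1)
  expect_equal(m[["sb_ratio"]], 5)
  expect_equal(p$t_df, 4)
  expect_length(p$reasons, 0)
})

test_that("undefined metrics are NA with reasons, never silent zeros", {
  ident <- metric_panel(control_groups(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$metrics[["t_stat"]], 0)
  expect_equal(ident$metrics[["ks_stat"]], 0)
  expect_equal(ident$metrics[["ssmd_mm"]], 0)
  expect_true(is.na(ident$metrics[["z_prime"]]))
  expect_match(ident$reasons[["z_prime"]], "equal")

  tiny <- metric_panel(control_groups(5, c(1, 2)))
  for (id in c("z_prime", "ssmd_mm", "ssmd_mle", "ssmd_robust",
               "t_stat", "t_pvalue", "cv_pos"))
    expect_true(is.na(tiny$metrics[[id]]), info = id)
  expect_false(is.na(tiny$metrics[["ks_stat"]]))
  expect_false(is.na(tiny$metrics[["sb_ratio"]]))
})

test_that("standardized metrics are affine-invariant, ratio metrics are not", {
  set.seed(5)
  invariant <- c("z_prime", "ssmd_mm", "ssmd_mle", "ssmd_robust",
                 "t_stat", "ks_stat")
  for (i in 1:10) {
    cg <- control_groups(rnorm(12, 10, 2), rnorm(14, 2, 1))
    a <- runif(1, 0.5, 4)
    b <- runif(1, -5, 5)
    cg2 <- control_groups(a * cg$pos + b, a * cg$neg + b)
    m1 <- metric_panel(cg)$metrics
    m2 <- metric_panel(cg2)$metrics
    for (id in invariant)
      expect_equal(m2[[id]], m1[[id]], tolerance = 1e-10, info = id)
    # S/B and CV must track the scale change instead
    expect_false(isTRUE(all.equal(m2[["sb_ratio"]], m1[["sb_ratio"]],
                                  tolerance = 1e-6)))
    expect_false(isTRUE(all.equal(m2[["cv_pos"]], m1[["cv_pos"]],
                                  tolerance = 1e-6)))
  }
})

test_that("separation increases Z' and all SSMDs monotonically", {
  pos0 <- c(9, 10, 11)
  neg <- c(1, 2, 3)
  shifts <- seq(0, 10, by = 2)
  zs <- mms <- mles <- robs <- numeric(length(shifts))
  for (i in seq_along(shifts)) {
    cg <- control_groups(pos0 + shifts[i], neg)
    zs[i] <- z_prime(cg); mms[i] <- ssmd_mm(cg)
    mles[i] <- ssmd_mle(cg); robs[i] <- ssmd_robust(cg)
  }
  expect_true(all(diff(zs) > 0))
  expect_true(all(diff(mms) > 0))
  expect_true(all(diff(mles) > 0))
  expect_true(all(diff(robs) > 0))
})

test_that("one 100-sigma outlier in 46 wells barely moves the robust SSMD", {
  set.seed(2024)
  pos <- rnorm(46, 8, 1)  # 8-sigma separation from the negatives
  neg <- rnorm(46, 0, 1)
  clean <- control_groups(pos, neg)
  pos_out <- pos
  pos_out[1] <- pos[1] + 100
  dirty <- control_groups(pos_out, neg)
  expect_lt(abs(ssmd_robust(dirty) - ssmd_robust(clean)) /
              abs(ssmd_robust(clean)), 0.10)
  expect_gt((abs(ssmd_mm(clean)) - abs(ssmd_mm(dirty))) /
              abs(ssmd_mm(clean)), 0.30)
})
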