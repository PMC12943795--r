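test_that("chain realization is exact in the noise-free limit", {
  cfg <- synthetic_config(
    n_samples = 100, n_exposures = 2, exposure_block_sizes = integer(0),
    n_phenotypes = 3, n_omics = 3,
    covariate_effects = numeric(0), seasonal_amplitude = 0, batch_sd = 0,
    missing_rate = 0, skew_fraction = 0,
    mediation_chains = list(chain_spec("D1", 1, 1, 1,
                                       a_path = 0.5, b_path = 0.4,
                                       direct_path = 0.1, noise_sd = 0)),
    seed = 11)
  b <- generate_cohort(cfg)
  x <- b$exposures[, 1]
  expect_equal(b$omics[, 1], 0.5 * x, tolerance = 1e-12, ignore_attr = TRUE)
  # outcome = 0.1 x + 0.4 (0.5 x) = 0.3 x elementwise
  expect_equal(b$phenotypes[, 1], 0.3 * x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("same config and seed give identical bundles; different seed differs", {
  cfg <- synthetic_config(n_samples = 120, seed = 5)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1, b2)
  b3 <- generate_cohort(synthetic_config(n_samples = 120, seed = 6))
  expect_false(identical(b1$phenotypes, b3$phenotypes))
})

test_that("exposure blocks hit the requested within-block correlation", {
  cfg <- synthetic_config(n_samples = 2000, n_exposures = 10,
                          exposure_block_sizes = 5L, within_block_r = 0.6,
                          missing_rate = 0, seed = 21)
  b <- generate_cohort(cfg)
  idx <- b$ground_truth$blocks[[1]]$columns
  r <- cor(b$exposures[, idx])
  mean_r <- mean(r[upper.tri(r)])
  expect_gt(mean_r, 0.55)
  expect_lt(mean_r, 0.65)
})

test_that("invalid configs are rejected naming the offending field", {
  expect_error(synthetic_config(within_block_r = 1.2), "within_block_r")
  expect_error(synthetic_config(missing_rate = -0.1), "missing_rate")
  expect_error(synthetic_config(batch_sd = -1), "batch_sd")
  expect_error(synthetic_config(n_exposures = 4, exposure_block_sizes = c(3, 3)),
               "exposure_block_sizes")
  expect_error(
    synthetic_config(mediation_chains = list(
      chain_spec("D1", 99, 1, 1, 0.5, 0.4))),
    "exposure_id")
})

test_that("inject_batch_and_season identity and cosine extrema", {
  m <- matrix(rnorm(60), 30, 2)
  day <- rep(1:3, each = 10)
  month <- rep(c(3, 9), 15)
  out <- inject_batch_and_season(m, day, month, batch_sd = 0, amplitude = 0)
  expect_equal(unclass(out), m, ignore_attr = TRUE)

  # amplitude 1, phase 3: month 3 at +1, month 9 at -1, difference 2
  z <- matrix(0, 12, 1)
  out2 <- inject_batch_and_season(z, rep(1, 12), 1:12, batch_sd = 0,
                                  amplitude = 1, phase = 3)
  expect_equal(out2[3, 1] - out2[9, 1], 2, tolerance = 1e-12)
  expect_error(inject_batch_and_season(m, day, month, batch_sd = -1), "batch_sd")
})

test_that("between-day variance of injected batch shifts matches batch_sd^2", {
  m <- matrix(0, 500, 1)
  day <- rep(1:10, each = 50)
  out <- inject_batch_and_season(m, day, rep(1, 500), batch_sd = 2,
                                 amplitude = 0, seed = 42)
  day_means <- tapply(out[, 1], day, mean)
  v <- var(day_means)
  # var of 10 draws from N(0, 4): chi-square spread, accept a generous band
  expect_gt(v, 1.2)
  expect_lt(v, 10)
  expect_equal(as.numeric(day_means), as.numeric(attr(out, "day_effects")),
               tolerance = 1e-12)
})

test_that("ground truth records every planted effect and chains are auditable", {
  chains <- list(
    chain_spec("D1", 1, 2, 3, a_path = 0.5, b_path = 0.4, direct_path = 0.1),
    chain_spec("D2", 2, 4, 5, a_path = -0.4, b_path = 0.3))
  cfg <- synthetic_config(n_samples = 1500, n_exposures = 6,
                          exposure_block_sizes = 3L, within_block_r = 0.5,
                          covariate_effects = numeric(0), seasonal_amplitude = 0,
                          batch_sd = 0, missing_rate = 0, skew_fraction = 0,
                          mediation_chains = chains, seed = 31)
  b <- generate_cohort(cfg)
  gt <- b$ground_truth
  expect_length(gt$blocks, 1)
  expect_length(gt$chains, 2)
  expect_equal(gt$seasonal$amplitude, 0)
  # audit: fitted a-path within 3 Monte-Carlo SEs of the planted value
  for (ch in gt$chains) {
    x <- b$exposures[, ch$exposure_id]
    m <- if (ch$direction == "D1") b$omics[, ch$mediator_id] else b$phenotypes[, ch$mediator_id]
    fit <- summary(lm(m ~ x))$coefficients
    expect_lt(abs(fit["x", "Estimate"] - ch$a_path), 3 * fit["x", "Std. Error"])
  }
})

test_that("skewed columns are right-skewed and missingness matches the rate", {
  cfg <- synthetic_config(n_samples = 800, missing_rate = 0.1,
                          skew_fraction = 0.4, seed = 41)
  b <- generate_cohort(cfg)
  sk_cols <- b$ground_truth$skewed_columns
  expect_gt(length(sk_cols), 0)
  sk <- vapply(sk_cols, function(j) sample_skewness(b$phenotypes[, j]), numeric(1))
  expect_true(all(sk > 0.5))
  expect_equal(mean(is.na(b$phenotypes)), 0.1, tolerance = 0.02)
})

test_that("write_cohort / read_cohort round-trip preserves the tables", {
  b <- generate_cohort(synthetic_config(n_samples = 40, n_phenotypes = 5,
                                        n_omics = 5, n_exposures = 6,
                                        exposure_block_sizes = 3L, seed = 51))
  d <- withr::local_tempdir()
  write_cohort(b, d)
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  back <- read_cohort(d)
  expect_equal(back$phenotypes, b$phenotypes, tolerance = 1e-10)
  expect_equal(back$covariates$gender, b$covariates$gender, ignore_attr = TRUE)
})
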