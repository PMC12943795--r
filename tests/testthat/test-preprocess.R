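test_that("sample skewness matches the hand formula and its symmetries", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0, tolerance = 1e-12)
  x <- c(1, 2, 3, 4, 100)
  n <- 5; mu <- mean(x)
  g1 <- mean((x - mu)^3) / mean((x - mu)^2)^1.5
  expect_equal(sample_skewness(x), g1 * sqrt(n * (n - 1)) / (n - 2), tolerance = 1e-12)
  set.seed(1); y <- rexp(50)
  expect_equal(sample_skewness(-y), -sample_skewness(y), tolerance = 1e-12)
  expect_error(sample_skewness(c(2, 2, 2)), "constant")
  expect_error(sample_skewness(c(1, 2)), "fewer than 3")
})

test_that("reflection triggers only on strong left skew and applies max+1-x", {
  right <- c(1, 1, 2, 2, 50)
  expect_equal(as.numeric(reflect_left_skewed(right)), right)
  expect_equal(as.numeric(reflect_left_skewed(c(0, 8, 9), threshold = 0.5)),
               c(10, 2, 1))
  # double reflection with forced branch: |skewness| preserved, sign flipped
  x <- c(0, 8, 9)
  r1 <- as.numeric(reflect_left_skewed(x, 0.5))
  expect_equal(abs(sample_skewness(r1)), abs(sample_skewness(x)), tolerance = 1e-12)
  expect_equal(sign(sample_skewness(r1)), -sign(sample_skewness(x)))
})

test_that("skew-gated outlier removal drives skewness under threshold", {
  set.seed(2)
  normal <- rnorm(500)
  r <- remove_skew_outliers(normal)
  expect_equal(sum(r$removed), 0)

  x <- c(1, 1, 2, 2, 3, 1000)
  expect_gt(sample_skewness(x), 2.15)
  r2 <- remove_skew_outliers(x)
  expect_true(r2$removed[6])
  expect_lte(sample_skewness(r2$x), 2.15)

  # cap: ~9% of points are extreme, only 5% may be removed
  set.seed(3)
  heavy <- c(rnorm(100), rep(1000, 10))
  r3 <- remove_skew_outliers(heavy)
  expect_lte(sum(r3$removed), ceiling(0.05 * 110))
  expect_true(r3$capped)
  expect_error(remove_skew_outliers(c(rep(NA, 6), 1, 2, 3)), "missing")
})

test_that("day batch correction removes a planted shift and keeps order", {
  set.seed(4)
  n <- 400
  day <- rep(c("d1", "d2"), each = n / 2)
  y <- rnorm(n, sd = 0.1) + ifelse(day == "d2", 1, 0)
  m <- matrix(y, ncol = 1)
  out <- batch_correct_day(m, day)
  gap <- abs(mean(out[day == "d2", 1]) - mean(out[day == "d1", 1]))
  expect_lt(gap, 0.05)
  expect_equal(mean(out), mean(m), tolerance = 1e-6)   # grand mean preserved
  # constant offset per day: within-day ordering untouched
  expect_equal(order(out[day == "d1", 1]), order(m[day == "d1", 1]))
  # single day: identity with a message
  expect_message(out1 <- batch_correct_day(m, rep("d1", n)), "single")
  expect_equal(out1, m)
})

test_that("inverse normal transform: Blom quantiles, ties, rank invariance", {
  x <- c(5, 1, 9, 3, 7)
  out <- inverse_normal_transform(x)
  expect_equal(out[1], 0)                                  # median -> 0
  expect_equal(out[3], qnorm((5 - 0.375) / 5.25), tolerance = 1e-12)
  expect_equal(inverse_normal_transform(exp(x)), out, tolerance = 1e-12)
  y <- c(2, NA, 1, 3)
  expect_true(is.na(inverse_normal_transform(y)[2]))
  expect_error(inverse_normal_transform(rep(1, 5)), "distinct")
})

test_that("kNN imputation: identity, zero-distance neighbours, beats mean imputation", {
  m <- matrix(rnorm(50), 10, 5)
  expect_identical(knn_impute(m, 3), m)

  row <- c(1.5, -0.3, 2.2, 0.4)
  dup <- matrix(rep(row, 7), nrow = 7, byrow = TRUE)
  dup <- rbind(dup, matrix(rnorm(12, sd = 5), 3, 4))
  dup[1, 3] <- NA
  expect_equal(knn_impute(dup, 5)[1, 3], row[3], tolerance = 1e-9)

  # smooth structure: kNN should beat per-feature mean imputation in RMSE
  set.seed(5)
  n <- 120; f <- rnorm(n)
  sm <- sapply(1:8, function(j) f * 0.9 + rnorm(n, sd = 0.3))
  miss <- matrix(runif(length(sm)) < 0.05, n, 8)
  obs <- sm; obs[miss] <- NA
  imp <- knn_impute(obs, 5)
  rmse_knn <- sqrt(mean((imp[miss] - sm[miss])^2))
  mean_imp <- obs
  for (j in 1:8) mean_imp[is.na(obs[, j]), j] <- mean(obs[, j], na.rm = TRUE)
  rmse_mean <- sqrt(mean((mean_imp[miss] - sm[miss])^2))
  expect_lt(rmse_knn, rmse_mean)

  bad <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(knn_impute(bad, 1), "missing in all rows")
  empty_row <- matrix(c(1, NA, 2, NA), 2, 2)
  expect_error(knn_impute(empty_row, 1), "at least one observed")
})

test_that("standardize matches hand arithmetic and affine invariance", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(20))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  x <- rnorm(30)
  expect_equal(standardize(3 * x + 7), standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("SD clipping masks the expected tail and respects the limit cases", {
  set.seed(6)
  m <- matrix(rnorm(10000), ncol = 1)
  cl <- clip_sd_outliers(m, 3)
  frac <- mean(cl$mask)
  expect_gt(frac, 0.0005)                     # normal tail ~0.27%
  expect_lt(frac, 0.006)
  spike <- matrix(c(rep(1, 50), rep(1.0001, 49), 100), ncol = 1)
  cl2 <- clip_sd_outliers(spike, 3)
  expect_equal(which(cl2$mask), 100)
  expect_equal(clip_sd_outliers(m, Inf)$matrix, m)
})

test_that("detection filter applies the fraction rule, empty input tolerated", {
  m <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[1:81, 1] <- NA     # 19% detected -> dropped
  m[1:79, 2] <- NA     # 21% detected -> kept
  out <- filter_detection(m, 0.2)
  expect_equal(out$kept, c("b", "c"))
  empty <- matrix(numeric(0), nrow = 10, ncol = 0)
  expect_equal(ncol(filter_detection(empty, 0.2)$matrix), 0)
})

test_that("energy extreme filter uses inclusive gender-specific bounds", {
  expect_false(filter_energy_extremes(4500, "male"))
  expect_false(filter_energy_extremes(400, "female"))
  expect_true(filter_energy_extremes(800, "male"))
  expect_true(filter_energy_extremes(4200, "male"))
  expect_true(filter_energy_extremes(500, "female"))
  expect_false(filter_energy_extremes(3600, "female"))
  expect_error(filter_energy_extremes(1000, "other"), "gender")
})

test_that("energy adjustment removes the energy component only", {
  set.seed(7)
  n <- 400
  energy <- rnorm(n, 2000, 300)
  indep <- rnorm(n)
  dep <- 0.8 * standardize(energy) + 0.6 * rnorm(n)
  truth <- rnorm(n)
  partial <- 0.5 * truth + 0.5 * standardize(energy)
  m <- cbind(indep = indep, same = energy, partial = partial)
  out <- energy_adjust(m, energy)
  expect_gt(abs(cor(out[, "indep"], standardize(indep))), 0.99)
  expect_lt(max(abs(out[, "same"])), 1e-10)
  expect_lt(abs(cor(out[, "partial"], energy)), 0.02)
  expect_gt(cor(out[, "partial"], truth), 0.5)
})

test_that("diet index scoring: tertiles, reversal symmetry, median subject", {
  groups <- names(default_food_groups())
  # 9 subjects, identical 1..9 pattern in every group
  ff <- matrix(rep(1:9, times = 16), nrow = 9,
               dimnames = list(NULL, groups))
  u <- score_pdi(ff, diet_score_spec("uPDI"))
  h <- score_pdi(ff, diet_score_spec("hPDI"))
  p <- score_pdi(ff, diet_score_spec("PDI"))
  # tertile rule on one unhealthful group under uPDI: 1-3 -> 1, 4-6 -> 3, 7-9 -> 5
  one_group <- ff[, "sugar", drop = FALSE]
  spec1 <- diet_score_spec("uPDI", group_class = c(sugar = "unhealthful_plant"))
  expect_equal(score_pdi(one_group, spec1), c(1, 1, 1, 3, 3, 3, 5, 5, 5))
  # middle subject sits in the middle tertile of every group: 16 x 3 = 48
  expect_equal(u[5], 48)
  expect_equal(h[5], 48)
  expect_equal(p[5], 48)
  # uPDI + hPDI group scores for a healthful group sum to 6 per subject
  spec_h <- diet_score_spec("hPDI", group_class = c(tea = "healthful_plant"))
  spec_u <- diet_score_spec("uPDI", group_class = c(tea = "healthful_plant"))
  tea <- ff[, "tea", drop = FALSE]
  expect_equal(score_pdi(tea, spec_h) + score_pdi(tea, spec_u), rep(6, 9))
  expect_error(score_pdi(ff[, -1], diet_score_spec("PDI")), "food group")
})

test_that("exposure inclusion requires more than 30 observations", {
  m <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[31:50, 1] <- NA       # 30 obs -> dropped
  m[32:50, 2] <- NA       # 31 obs -> kept
  m[, 3] <- NA            # all missing -> dropped
  out <- exposure_inclusion_filter(m)
  expect_equal(colnames(out), "b")
})

test_that("preprocess pipeline is idempotent on its own output", {
  cfg <- synthetic_config(n_samples = 150, n_phenotypes = 8, batch_count = 5,
                          batch_sd = 0.5, missing_rate = 0.03,
                          skew_fraction = 0.5, seed = 61)
  b <- generate_cohort(cfg)
  p1 <- preprocess_phenotypes(b$phenotypes, b$covariates$sampling_day)
  p2 <- preprocess_phenotypes(p1$matrix, b$covariates$sampling_day)
  expect_lt(max(abs(p2$matrix - p1$matrix)), 1e-10)
  expect_true(all(p1$report$transform %in% c("INT", "standardize")))
})
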