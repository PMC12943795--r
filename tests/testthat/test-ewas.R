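test_that("BH adjustment matches the hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- sort(runif(20))
  expect_false(is.unsorted(bh_adjust(p)))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("fit_association recovers planted effects and flags degeneracy", {
  set.seed(1)
  n <- 1000
  cov <- make_covariate_frame(make_covars(n))
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  f <- fit_association(y, x, cov)
  expect_gt(f$coefficient, 0.24); expect_lt(f$coefficient, 0.36)
  expect_lt(f$t_p, 1e-10)

  # y duplicated as x: perfect fit, p at the floor
  fp <- fit_association(y, y, NULL)
  expect_equal(fp$coefficient, 1, tolerance = 1e-10)
  expect_equal(fp$t_p, 1e-300)

  cov2 <- cov; cov2$age2 <- cov2$age * 2
  expect_error(fit_association(y, x, cov2), "collinear")
  expect_error(fit_association(y[1:8], x[1:8], cov[1:8, ]), "complete cases")
  expect_error(fit_association(y[1:8], x[1:8], cov), "same length")
})

test_that("fast path of run_ewas equals the per-pair lm fit", {
  set.seed(2)
  n <- 150
  covars <- make_covars(n, seed = 3)
  cf <- make_covariate_frame(covars)
  Y <- matrix(rnorm(n * 3), n, 3, dimnames = list(rownames(covars), paste0("y", 1:3)))
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(rownames(covars), paste0("x", 1:2)))
  Y[, 1] <- 0.4 * X[, 1] + rnorm(n)
  fast <- run_ewas(Y, X, cf)
  for (r in seq_len(nrow(fast))) {
    ref <- lm(Y[, fast$phenotype[r]] ~ X[, fast$exposure[r]] + age + gender + season,
              data = cf)
    cc <- summary(ref)$coefficients[2, ]
    expect_equal(fast$coefficient[r], unname(cc[1]), tolerance = 1e-10)
    expect_equal(fast$se[r], unname(cc[2]), tolerance = 1e-10)
    expect_equal(fast$t_p[r], unname(cc[4]), tolerance = 1e-9)
  }
  # missing data falls back to listwise deletion with matching answers
  Y2 <- Y; Y2[1, 2] <- NA
  slow <- run_ewas(Y2, X, cf)
  both <- fast$exposure == "x1" & fast$phenotype == "y1"
  expect_equal(slow$coefficient[both], fast$coefficient[both], tolerance = 1e-10)
  expect_equal(slow$n_used[slow$phenotype == "y2"], rep(n - 1L, 2))
})

test_that("run_ewas flags the planted pair and contracts hold", {
  set.seed(4)
  n <- 500
  covars <- make_covars(n, seed = 5)
  cf <- make_covariate_frame(covars)
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(rownames(covars), paste0("x", 1:20)))
  Y <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(rownames(covars), paste0("y", 1:10)))
  Y[, 1] <- 0.4 * X[, 1] + rnorm(n)
  res <- run_ewas(Y, X, cf)
  hit <- res[res$exposure == "x1" & res$phenotype == "y1", ]
  expect_true(hit$significant)
  nulls <- res[!(res$exposure == "x1" & res$phenotype == "y1"), ]
  expect_lt(mean(nulls$significant), 0.1)

  empty <- run_ewas(Y, X[, 0, drop = FALSE], cf)
  expect_equal(nrow(empty), 0)
  Xs <- X; rownames(Xs) <- rev(rownames(X))
  expect_error(run_ewas(Y, Xs, cf), "aligned")
})

test_that("LRT and coefficient-test p-values agree in -log10", {
  set.seed(6)
  n <- 300
  res <- run_ewas(matrix(rnorm(n * 20), n, 20, dimnames = list(sprintf("S%05d", 1:n), NULL)),
                  matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("S%05d", 1:n), NULL)))
  expect_gt(cor(-log10(res$t_p), -log10(res$lrt_p)), 0.99)
})

test_that("association is invariant to affine rescaling of covariates", {
  set.seed(7)
  n <- 300
  cov <- data.frame(age = runif(n, 20, 60), z = rnorm(n))
  x <- rnorm(n); y <- 0.3 * x + 0.2 * cov$z + rnorm(n)
  f1 <- fit_association(y, x, cov)
  cov2 <- data.frame(age = cov$age / 10 + 3, z = 5 * cov$z - 1)
  f2 <- fit_association(y, x, cov2)
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-8)
  expect_equal(f1$t_p, f2$t_p, tolerance = 1e-8)
})

test_that("stratified EWAS splits correctly and age 40 goes to the older stratum", {
  set.seed(8)
  n <- 400
  covars <- make_covars(n, seed = 9)
  covars$age[1] <- 40
  cf0 <- make_covariate_frame(covars)
  Y <- matrix(rnorm(n * 2), n, 2, dimnames = list(rownames(covars), c("y1", "y2")))
  X <- matrix(rnorm(n), n, 1, dimnames = list(rownames(covars), "x1"))
  strat <- stratified_ewas(Y, X, cf0, strata = "age")
  n_old <- sum(covars$age >= 40)
  expect_equal(unique(strat$age_ge_40$n_used), n_old)
  expect_setequal(names(strat), c("age_lt_40", "age_ge_40"))
  # tiny stratum skipped with a message
  covars2 <- covars; covars2$gender <- factor(c(rep("male", n - 5), rep("female", 5)),
                                              levels = c("female", "male"))
  cf2 <- make_covariate_frame(covars2)
  expect_message(s2 <- stratified_ewas(Y, X, cf2, strata = "gender"), "skipped")
  expect_equal(names(s2), "male")
})

test_that("resampling stability saturates for strong effects, seed fixes the stream", {
  set.seed(10)
  n <- 400
  x <- rnorm(n); y <- 1.0 * x + rnorm(n, sd = 0.3)
  r1 <- resample_stability(y, x, fraction = 0.9, n_iter = 20, seed = 99)
  expect_equal(r1$n_significant, 20)
  r2 <- resample_stability(y, x, fraction = 0.9, n_iter = 20, seed = 99)
  expect_identical(r1, r2)
})

test_that("sensitivity adjustment: empty extra is identity, mediator attenuates", {
  set.seed(11)
  n <- 600
  x <- rnorm(n)
  bmi <- 0.9 * x + rnorm(n, sd = 0.3)   # pathway variable
  y <- 0.5 * bmi + rnorm(n, sd = 0.5)
  base <- fit_association(y, x, NULL)
  s0 <- sensitivity_adjust(y, x, NULL, extra = NULL)
  expect_equal(s0$coefficient, base$coefficient)
  s1 <- sensitivity_adjust(y, x, NULL, extra = data.frame(bmi = bmi))
  expect_lt(abs(s1$coefficient), abs(base$coefficient) / 2)
  # PC selection keeps only phenotype-associated columns
  pcs <- data.frame(pc1 = 0.7 * y + rnorm(n), pc2 = rnorm(n))
  s2 <- sensitivity_adjust(y, x, NULL, extra = pcs, select_pcs = TRUE)
  expect_true("pc1" %in% s2$covariates_used)
  expect_false("pc2" %in% s2$covariates_used)
})

test_that("basic factor tests recover age and gender effects", {
  set.seed(12)
  n <- 400
  covars <- make_covars(n, seed = 13)
  age_driven <- standardize(covars$age) + rnorm(n, sd = 0.8)
  gender_driven <- (covars$gender == "male") * 1.0 + rnorm(n, sd = 0.5)
  null_f <- rnorm(n)
  Y <- cbind(a = age_driven, g = gender_driven, z = null_f)
  rownames(Y) <- rownames(covars)
  res <- basic_factor_tests(Y, covars)
  expect_gt(res$age_rho[1], 0.3)
  expect_lt(res$age_fdr[1], 0.01)
  expect_lt(res$gender_fdr[2], 0.01)
  expect_gt(res$gender_fdr[3], 0.05)
  Yc <- Y; Yc[, 3] <- 1
  expect_error(basic_factor_tests(Yc, covars), "constant")
})

test_that("cosinor fit recovers planted rhythms incl. phase wrap-around", {
  mo <- rep(1:12, each = 8)
  y <- 0.5 + 0.3 * cos(2 * pi * (mo - 3) / 12)
  f <- cosinor_fit(y, mo)
  expect_equal(f$mesor, 0.5, tolerance = 1e-8)
  expect_equal(f$amplitude, 0.3, tolerance = 1e-8)
  expect_equal(f$phase, 3, tolerance = 1e-8)

  y2 <- 1 + 0.4 * cos(2 * pi * (mo - 11.5) / 12)
  f2 <- cosinor_fit(y2, mo)
  expect_equal(f2$phase, 11.5, tolerance = 1e-6)

  set.seed(14)
  flat <- rnorm(96, 5, 1)
  ff <- cosinor_fit(flat, mo)
  expect_lt(ff$amplitude_norm, 0.15)
  expect_gt(ff$rhythm_p, 0.001)
  expect_error(cosinor_fit(rnorm(10), rep(1, 10)), "distinct months")
})

test_that("MEQ chronotype cutpoints", {
  expect_equal(as.character(meq_stratify(c(41, 59, 50, 30, 70, NA))),
               c("evening", "morning", "middle", "evening", "morning", NA))
})
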