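# Exposure-wide association: covariate-adjusted linear models with
# coefficient t-tests and likelihood-ratio tests, BH-FDR, stratified,
# resampling-stability, sensitivity, basic-factor and seasonal analyses.

#' Build the default covariate design
#'
#' Age enters linearly, gender as a factor, and season as month-of-year
#' categorical (11 dummies) — the least-assumption coding; `season_coding =
#' "harmonic"` swaps in a single cosine/sine pair.
#'
#' @param covariates data frame with (a subset of) `age`, `gender`, `month`.
#' @param season_coding `"month"` or `"harmonic"`.
#' @return data frame ready for `model.matrix(~ .)`.
#' @export
make_covariate_frame <- function(covariates, season_coding = c("month", "harmonic")) {
  season_coding <- match.arg(season_coding)
  out <- data.frame(row.names = rownames(covariates))
  if (!is.null(covariates$age)) out$age <- covariates$age
  if (!is.null(covariates$gender)) out$gender <- factor(covariates$gender)
  if (!is.null(covariates$month)) {
    if (season_coding == "month") {
      out$season <- factor(covariates$month, levels = sort(unique(covariates$month)))
    } else {
      out$season_cos <- cos(2 * pi * covariates$month / 12)
      out$season_sin <- sin(2 * pi * covariates$month / 12)
    }
  }
  out
}

# Fit y ~ [C, x] and y ~ C on the complete cases; returns coef stats + LRT.
fit_pair <- function(y, x, C) {
  if (length(x) != length(y) || nrow(C) != length(y))
    stop("y, x and the covariate design must have the same length", call. = FALSE)
  ok <- !is.na(y) & !is.na(x) & stats::complete.cases(C)
  n <- sum(ok)
  p_full <- ncol(C) + 1L
  if (n < p_full + 10) stop("too few complete cases for the model", call. = FALSE)
  Cc <- C[ok, , drop = FALSE]
  X <- cbind(Cc, x = x[ok])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  yv <- y[ok]
  fit <- stats::lm.fit(X, yv)
  rss1 <- sum(fit$residuals^2)
  fit0 <- stats::lm.fit(Cc, yv)
  rss0 <- sum(fit0$residuals^2)
  df_res <- n - ncol(X)
  sigma2 <- rss1 / df_res
  XtXinv_xx <- solve(crossprod(X))[ncol(X), ncol(X)]
  beta <- fit$coefficients[["x"]]
  se <- sqrt(sigma2 * XtXinv_xx)
  t_p <- floor_p(2 * stats::pt(abs(beta / se), df_res, lower.tail = FALSE))
  lrt <- n * (log(rss0) - log(rss1))
  lrt_p <- floor_p(stats::pchisq(lrt, df = 1, lower.tail = FALSE))
  list(coefficient = beta, se = se, t_p = t_p, lrt_p = lrt_p, n_used = n)
}

#' Covariate-adjusted association of one exposure with one phenotype
#'
#' Full model `phenotype ~ exposure + covariates`, null model
#' `phenotype ~ covariates`; coefficient t-test and likelihood-ratio test
#' (chi-square, 1 df) with listwise deletion of missing values.
#'
#' @param y phenotype vector.
#' @param x exposure vector.
#' @param covariates covariate data frame (see [make_covariate_frame()]),
#'   or `NULL` for an intercept-only null model.
#' @return list: `coefficient`, `se`, `t_p`, `lrt_p`, `n_used`.
#' @export
fit_association <- function(y, x, covariates = NULL) {
  C <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  fit_pair(y, x, C)
}

#' Exposure-wide association scan
#'
#' Fits every exposure x phenotype pair, then applies Benjamini-Hochberg
#' across all pairs separately to the coefficient-test and LRT p-values.
#' A pair is flagged significant when the coefficient FDR is below
#' `fdr_threshold`. Tables must share row names (sample IDs).
#'
#' @param phenotypes samples x phenotypes matrix.
#' @param exposures samples x exposures matrix.
#' @param covariates covariate data frame or `NULL`.
#' @param fdr_threshold significance threshold on the coefficient FDR.
#' @return data frame: exposure, phenotype, coefficient, se, t_p, lrt_p,
#'   n_used, fdr_coef, fdr_lrt, significant.
#' @export
run_ewas <- function(phenotypes, exposures, covariates = NULL, fdr_threshold = 0.05) {
  Y <- as_num_matrix(phenotypes, "phenotypes")
  X <- as_num_matrix(exposures, "exposures")
  if (ncol(X) == 0 || ncol(Y) == 0) {
    return(data.frame(exposure = character(0), phenotype = character(0),
                      coefficient = numeric(0), se = numeric(0),
                      t_p = numeric(0), lrt_p = numeric(0),
                      n_used = integer(0), fdr_coef = numeric(0),
                      fdr_lrt = numeric(0), significant = logical(0)))
  }
  if (!is.null(covariates)) assert_aligned(Y, X, as.data.frame(covariates)) else assert_aligned(Y, X)
  C <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    matrix(1, nrow(Y), 1, dimnames = list(rownames(Y), "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  en <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  pn <- colnames(Y) %||% paste0("y", seq_len(ncol(Y)))

  if (!anyNA(Y) && !anyNA(X)) {
    # complete data: Frisch-Waugh fast path, algebraically identical to the
    # per-pair fit (residualize once on the covariate design)
    qC <- qr(C)
    Ry <- qr.resid(qC, Y)
    Rx <- qr.resid(qC, X)
    n <- nrow(Y)
    pC <- qC$rank
    df_res <- n - pC - 1L
    xtx <- colSums(Rx^2)
    bet <- crossprod(Rx, Ry) / xtx                    # exposures x phenotypes
    yty <- colSums(Ry^2)
    rss1 <- outer(xtx, rep(1, ncol(Y))) * bet^2 * -1 +
      matrix(yty, ncol(X), ncol(Y), byrow = TRUE)
    rss0 <- matrix(yty, ncol(X), ncol(Y), byrow = TRUE)
    se <- sqrt(rss1 / df_res / xtx)
    tstat <- bet / se
    t_p <- floor_p(2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE))
    lrt_p <- floor_p(stats::pchisq(n * (log(rss0) - log(rss1)), 1, lower.tail = FALSE))
    res <- data.frame(
      exposure = rep(en, times = ncol(Y)),
      phenotype = rep(pn, each = ncol(X)),
      coefficient = as.vector(bet), se = as.vector(se),
      t_p = as.vector(t_p), lrt_p = as.vector(lrt_p),
      n_used = n, stringsAsFactors = FALSE)
  } else {
    rows <- vector("list", ncol(X) * ncol(Y))
    k <- 1L
    for (jy in seq_len(ncol(Y))) for (jx in seq_len(ncol(X))) {
      f <- fit_pair(Y[, jy], X[, jx], C)
      rows[[k]] <- data.frame(exposure = en[jx], phenotype = pn[jy],
                              coefficient = f$coefficient, se = f$se,
                              t_p = f$t_p, lrt_p = f$lrt_p, n_used = f$n_used,
                              stringsAsFactors = FALSE)
      k <- k + 1L
    }
    res <- do.call(rbind, rows)
  }
  res$fdr_coef <- bh_adjust(res$t_p)
  res$fdr_lrt <- bh_adjust(res$lrt_p)
  res$significant <- res$fdr_coef < fdr_threshold
  rownames(res) <- NULL
  res
}

#' Stratified exposure-wide association
#'
#' Reruns [run_ewas()] within gender strata (male vs female) or age strata
#' (< 40 vs >= 40); the stratification variable is dropped from the
#' covariates. Strata with fewer than `min_n` samples are skipped with a
#' message.
#'
#' @param phenotypes,exposures,covariates as in [run_ewas()]; `covariates`
#'   must contain the stratification variable.
#' @param strata `"gender"` or `"age"`.
#' @param min_n minimum stratum size (default 30).
#' @return named list of per-stratum association tables, each with a
#'   `stratum` column.
#' @export
stratified_ewas <- function(phenotypes, exposures, covariates,
                            strata = c("gender", "age"), min_n = 30L) {
  strata <- match.arg(strata)
  cov <- as.data.frame(covariates)
  lab <- if (strata == "gender") {
    as.character(cov$gender)
  } else {
    ifelse(cov$age >= 40, "age_ge_40", "age_lt_40")
  }
  keep_cov <- setdiff(names(cov), if (strata == "gender") "gender" else "age")
  out <- list()
  for (s in sort(unique(lab))) {
    idx <- which(lab == s)
    if (length(idx) < min_n) {
      message(sprintf("stratum '%s' skipped: n = %d < %d", s, length(idx), min_n))
      next
    }
    tab <- run_ewas(phenotypes[idx, , drop = FALSE],
                    exposures[idx, , drop = FALSE],
                    if (length(keep_cov)) cov[idx, keep_cov, drop = FALSE] else NULL)
    tab$stratum <- s
    out[[s]] <- tab
  }
  out
}

#' Resampling stability of one association
#'
#' Repeatedly refits the pair on random subsamples (without replacement) of
#' `fraction` of the samples and records how often p < 0.05, plus the mean
#' p-value and coefficient.
#'
#' @param y,x,covariates as in [fit_association()].
#' @param fraction subsample fraction, typically 0.9 or 0.8.
#' @param n_iter number of subsamples (default 100).
#' @param seed integer seed fixing the subsample stream.
#' @return list: `n_significant`, `mean_p`, `mean_coefficient`, `fraction`,
#'   `n_iter`.
#' @export
resample_stability <- function(y, x, covariates = NULL, fraction = 0.9,
                               n_iter = 100L, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  m <- floor(fraction * n)
  ps <- coefs <- numeric(n_iter)
  cov <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  for (i in seq_len(n_iter)) {
    idx <- sample.int(n, m)
    f <- fit_association(y[idx], x[idx],
                         if (is.null(cov)) NULL else cov[idx, , drop = FALSE])
    ps[i] <- f$t_p
    coefs[i] <- f$coefficient
  }
  list(n_significant = sum(ps < 0.05), mean_p = mean(ps),
       mean_coefficient = mean(coefs), fraction = fraction, n_iter = n_iter)
}

#' Sensitivity reanalysis with extra covariates
#'
#' Refits the association with an extended covariate set (e.g. BMI, COVID-19
#' infection/vaccination indicators). For genetic principal components, pass
#' `select_pcs = TRUE`: only the PCs marginally associated with the phenotype
#' (p < 0.05) are added, mirroring the screen-then-adjust protocol.
#'
#' @param y,x,covariates as in [fit_association()].
#' @param extra data frame of additional covariates (may be genetic PCs).
#' @param select_pcs screen `extra` columns on marginal association with `y`
#'   before adjusting.
#' @return as [fit_association()], plus `covariates_used`.
#' @export
sensitivity_adjust <- function(y, x, covariates = NULL, extra = NULL,
                               select_pcs = FALSE) {
  extra <- if (is.null(extra)) NULL else as.data.frame(extra)
  if (!is.null(extra) && select_pcs) {
    keep <- vapply(extra, function(pc) {
      ok <- !is.na(y) & !is.na(pc)
      f <- stats::summary.lm(stats::lm(y[ok] ~ pc[ok]))
      f$coefficients[2, 4] < 0.05
    }, logical(1))
    extra <- extra[keep]
    if (ncol(extra) == 0) extra <- NULL
  }
  cov <- if (is.null(covariates)) extra else {
    if (is.null(extra)) as.data.frame(covariates) else cbind(as.data.frame(covariates), extra)
  }
  out <- fit_association(y, x, cov)
  out$covariates_used <- if (is.null(cov)) character(0) else names(cov)
  out
}

#' Age, gender and season effects on each phenotype
#'
#' Per phenotype: Spearman correlation with age after residualizing gender
#' and season; Welch two-sample t-test between genders after residualizing
#' age and season. Each family of p-values is BH-adjusted.
#'
#' @param phenotypes samples x phenotypes matrix.
#' @param covariates data frame with `age`, `gender`, `month`.
#' @return data frame: phenotype, age_rho, age_p, age_fdr, gender_diff,
#'   gender_p, gender_fdr.
#' @export
basic_factor_tests <- function(phenotypes, covariates) {
  Y <- as_num_matrix(phenotypes, "phenotypes")
  cov <- as.data.frame(covariates)
  season <- factor(cov$month)
  gender <- factor(cov$gender)
  age <- cov$age
  pn <- colnames(Y) %||% paste0("y", seq_len(ncol(Y)))
  out <- data.frame(phenotype = pn, age_rho = NA_real_, age_p = NA_real_,
                    gender_diff = NA_real_, gender_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    ok <- !is.na(y)
    if (stats::sd(y[ok]) == 0)
      stop(sprintf("constant phenotype: %s", pn[j]), call. = FALSE)
    r_g <- stats::residuals(stats::lm(y ~ gender + season, subset = ok))
    ct <- suppressWarnings(stats::cor.test(r_g, age[ok], method = "spearman", exact = FALSE))
    out$age_rho[j] <- unname(ct$estimate)
    out$age_p[j] <- ct$p.value
    r_a <- stats::residuals(stats::lm(y ~ age + season, subset = ok))
    tt <- stats::t.test(r_a[gender[ok] == levels(gender)[2]],
                        r_a[gender[ok] == levels(gender)[1]])
    out$gender_diff[j] <- unname(tt$estimate[1] - tt$estimate[2])
    out$gender_p[j] <- tt$p.value
  }
  out$age_fdr <- bh_adjust(out$age_p)
  out$gender_fdr <- bh_adjust(out$gender_p)
  out
}

#' Cosinor fit of a 12-month seasonal rhythm
#'
#' Min-max normalizes the phenotype, fits
#' `y = k + alpha * cos(2*pi*(t - phi)/12)` by least squares through the
#' linear reparameterization in `cos(2*pi*t/12)` and `sin(2*pi*t/12)`, and
#' tests the rhythm with the F-test of both harmonic coefficients. Mesor and
#' amplitude are reported back on the original scale (the normalization is an
#' affine map); the phase is scale-free.
#'
#' @param y phenotype vector.
#' @param month per-sample month of year (values in `[0, 12)` or 1-12).
#' @return list of class `cosinor_fit`: `mesor`, `amplitude`, `phase`
#'   (peak month in `[0, 12)`), `rhythm_p`, plus the normalized-scale
#'   `mesor_norm` / `amplitude_norm`.
#' @export
cosinor_fit <- function(y, month) {
  ok <- !is.na(y) & !is.na(month)
  y <- y[ok]; month <- month[ok]
  if (length(unique(month)) < 3)
    stop("cosinor fit requires at least 3 distinct months", call. = FALSE)
  rng <- range(y)
  if (rng[1] == rng[2]) stop("constant phenotype", call. = FALSE)
  yn <- (y - rng[1]) / (rng[2] - rng[1])
  cc <- cos(2 * pi * month / 12)
  ss <- sin(2 * pi * month / 12)
  fit <- stats::lm(yn ~ cc + ss)
  b <- stats::coef(fit)
  amp_n <- sqrt(b[["cc"]]^2 + b[["ss"]]^2)
  phase <- (12 / (2 * pi)) * atan2(b[["ss"]], b[["cc"]])
  phase <- phase %% 12
  f <- suppressWarnings(stats::summary.lm(fit))$fstatistic
  rhythm_p <- if (is.null(f)) 1 else
    floor_p(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  scale_ <- rng[2] - rng[1]
  structure(list(mesor = b[["(Intercept)"]] * scale_ + rng[1],
                 amplitude = amp_n * scale_,
                 phase = phase,
                 period = 12,
                 rhythm_p = unname(rhythm_p),
                 mesor_norm = b[["(Intercept)"]],
                 amplitude_norm = amp_n),
            class = "cosinor_fit")
}

#' Chronotype labels from MEQ scores
#'
#' Morningness-Eveningness Questionnaire cutpoints: score <= 41 evening
#' chronotype, >= 59 morning chronotype, otherwise middle.
#'
#' @param meq_scores numeric MEQ scores.
#' @return factor with levels evening, middle, morning (`NA` preserved).
#' @export
meq_stratify <- function(meq_scores) {
  lab <- ifelse(meq_scores <= 41, "evening",
                ifelse(meq_scores >= 59, "morning", "middle"))
  factor(lab, levels = c("evening", "middle", "morning"))
}
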