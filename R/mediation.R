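# Bidirectional causal mediation for (exposure, omic, immunophenotype)
# triples: dual-correlation candidate screening, interaction-aware two-model
# fits, nonparametric bootstrap ACME/ADE/total/proportion, and D1/D2
# direction classification.
#
# D1: exposure -> omic (mediator) -> immunophenotype (outcome).
# D2: exposure -> immunophenotype (mediator) -> omic (outcome).

#' Screen omics features as mediation candidates
#'
#' Keeps the omics features whose Spearman correlation passes BH-FDR < `fdr`
#' both with the exposure and with the immunophenotype (each FDR computed
#' across all omics features of the screen). Inputs should already be
#' residualized on the basic covariates.
#'
#' @param exposure exposure vector.
#' @param phenotype immunophenotype vector.
#' @param omics samples x features omics matrix.
#' @param fdr dual FDR threshold (default 0.05).
#' @return character vector (or indices) of candidate features.
#' @export
screen_candidates <- function(exposure, phenotype, omics, fdr = 0.05) {
  omics <- as_num_matrix(omics, "omics")
  if (ncol(omics) == 0) return(character(0))
  p_with <- function(v) {
    apply(omics, 2, function(o) {
      ok <- !is.na(o) & !is.na(v)
      if (sum(ok) < 4) return(NA_real_)
      suppressWarnings(stats::cor.test(o[ok], v[ok], method = "spearman",
                                       exact = FALSE)$p.value)
    })
  }
  fdr_x <- bh_adjust(p_with(exposure))
  fdr_y <- bh_adjust(p_with(phenotype))
  keep <- !is.na(fdr_x) & !is.na(fdr_y) & fdr_x < fdr & fdr_y < fdr
  (colnames(omics) %||% seq_len(ncol(omics)))[keep]
}

# OLS point estimates of the two mediation models:
# mediator model m ~ 1 + x, outcome model y ~ 1 + x + m + x:m.
#
# Both fits (and every bootstrap refit) only need sums of products of the
# columns of a fixed n x 13 product matrix, so a bootstrap draw reduces to
# one crossprod of the resample counts with that matrix - much cheaper than
# re-running a QR decomposition per draw.
mediation_products <- function(x, m, y) {
  v <- x * m
  cbind(x = x, m = m, y = y, v = v,
        xx = x * x, xm = x * m, xv = x * v,
        mm = m * m, mv = m * v, vv = v * v,
        xy = x * y, my = m * y, vy = v * y)
}

mediation_from_sums <- function(s, n) {
  XtX <- matrix(c(n,       s["x"],  s["m"],  s["v"],
                  s["x"],  s["xx"], s["xm"], s["xv"],
                  s["m"],  s["xm"], s["mm"], s["mv"],
                  s["v"],  s["xv"], s["mv"], s["vv"]), 4, 4)
  Xty <- c(s["y"], s["xy"], s["my"], s["vy"])
  cf <- tryCatch(solve(XtX, Xty), error = function(e)
    stop("degenerate (collinear) mediation design", call. = FALSE))
  b1 <- (s["xm"] - s["x"] * s["m"] / n) / (s["xx"] - s["x"]^2 / n)
  acme <- b1 * cf[3]
  c(beta1 = unname(b1), beta2 = unname(cf[3]), gamma1 = unname(cf[2]),
    delta2 = unname(cf[4]), acme = unname(acme), ade = unname(cf[2]),
    total = unname(cf[2] + acme))
}

mediation_point <- function(x, m, y) {
  P <- mediation_products(x, m, y)
  mediation_from_sums(colSums(P), length(x))
}

# Vectorized ACME over a matrix of bootstrap sufficient statistics (one row
# per draw): the centered 3x3 outcome-model system is solved for the
# mediator slope by Cramer's rule, elementwise across draws.
boot_acme_from_sums <- function(S, n) {
  cc <- function(ab, a, b) S[, ab] - S[, a] * S[, b] / n
  Cxx <- cc("xx", "x", "x"); Cxm <- cc("xm", "x", "m"); Cxv <- cc("xv", "x", "v")
  Cmm <- cc("mm", "m", "m"); Cmv <- cc("mv", "m", "v"); Cvv <- cc("vv", "v", "v")
  Cxy <- cc("xy", "x", "y"); Cmy <- cc("my", "m", "y"); Cvy <- cc("vy", "v", "y")
  det_a <- Cxx * (Cmm * Cvv - Cmv^2) -
    Cxm * (Cxm * Cvv - Cmv * Cxv) +
    Cxv * (Cxm * Cmv - Cmm * Cxv)
  det_b2 <- Cxx * (Cmy * Cvv - Cvy * Cmv) -
    Cxy * (Cxm * Cvv - Cmv * Cxv) +
    Cxv * (Cxm * Cvy - Cmy * Cxv)
  acme <- (Cxm / Cxx) * (det_b2 / det_a)
  acme[!is.finite(acme)] <- NA_real_
  acme
}

#' Fit one mediation triple with a bootstrap ACME
#'
#' Variables are centered (but not rescaled: effects stay on the input
#' scale, which the upstream pipeline has already standardized), then two
#' linear models are fitted: the mediator model `m ~ x` and the outcome model
#' `y ~ x + m + x:m` (the interaction is estimated at the centering point, so
#' the mediator slope `beta2` and exposure slope `gamma1` are average-level
#' effects). The average causal mediation effect is `ACME = beta1 * beta2`,
#' the average direct effect `ADE = gamma1`, the total effect their sum, and
#' the mediation proportion `ACME / total` (capped to `[-1, 1]` for
#' reporting; the raw ratio is kept in `proportion_raw`). Uncertainty comes
#' from a nonparametric paired-row bootstrap of the whole two-model fit:
#' percentile CI and a two-sided sign-based p-value floored at `1/n_boot`.
#'
#' @param x exposure, `m` mediator, `y` outcome (aligned vectors; complete
#'   triples are used and must number at least 50).
#' @param n_boot bootstrap draws (default 1000; fewer than 100 warns).
#' @param seed integer seed for the bootstrap stream (the point estimates do
#'   not depend on it).
#' @return list of class `mediation_fit`: coefficients, `acme`, `ade`,
#'   `total`, `proportion`, `proportion_raw`, `ci` (2.5%, 97.5% of ACME),
#'   `boot_p`, `n_boot`, `n_used`.
#' @export
fit_mediation <- function(x, m, y, n_boot = 1000L, seed = NULL) {
  ok <- !is.na(x) & !is.na(m) & !is.na(y)
  if (sum(ok) < 50) stop("fewer than 50 complete triples", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: bootstrap CI will be unstable")
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  for (v in list(x = x, m = m, y = y)) {
    if (stats::sd(v) == 0) stop("degenerate (constant) variable in mediation triple", call. = FALSE)
  }
  x <- x - mean(x); m <- m - mean(m); y <- y - mean(y)
  n <- length(x)

  pt <- mediation_point(x, m, y)
  prop_raw <- if (pt[["total"]] != 0) pt[["acme"]] / pt[["total"]] else NA_real_
  prop <- if (is.na(prop_raw)) NA_real_ else max(-1, min(1, prop_raw))

  if (!is.null(seed)) set.seed(seed)
  P <- mediation_products(x, m, y)
  # batched bootstrap: one tabulate() builds the resample-count matrix for a
  # whole chunk of draws, and one crossprod() yields every draw's sufficient
  # statistics; chunking caps the count-matrix size at ~4e6 cells
  boot_acme <- numeric(n_boot)
  chunk <- max(1L, min(n_boot, as.integer(4e6 / n)))
  done <- 0L
  while (done < n_boot) {
    b_now <- min(chunk, n_boot - done)
    idx <- sample.int(n, n * b_now, replace = TRUE)
    bins <- idx + rep.int(seq_len(b_now) - 1L, rep.int(n, b_now)) * n
    W <- matrix(tabulate(bins, nbins = n * b_now), n, b_now)
    S <- crossprod(W, P)                       # draws x sufficient statistics
    boot_acme[done + seq_len(b_now)] <- boot_acme_from_sums(S, n)
    done <- done + b_now
  }
  boot_acme <- boot_acme[!is.na(boot_acme)]
  ci <- stats::quantile(boot_acme, c(0.025, 0.975), names = FALSE)
  boot_p <- max(2 * min(mean(boot_acme <= 0), mean(boot_acme >= 0)), 1 / n_boot)

  structure(list(beta1 = pt[["beta1"]], beta2 = pt[["beta2"]],
                 gamma1 = pt[["gamma1"]], delta2 = pt[["delta2"]],
                 acme = pt[["acme"]], ade = pt[["ade"]], total = pt[["total"]],
                 proportion = prop, proportion_raw = prop_raw,
                 ci = ci, boot_p = boot_p, n_boot = n_boot, n_used = n),
            class = "mediation_fit")
}

#' Classify the mediation direction of a triple
#'
#' D1 when the D1 FDR is below `fdr_cut` and the D1 proportion exceeds the
#' D2 proportion; D2 symmetrically; otherwise none. Proportions are compared
#' in absolute value by default (they can be negative under inconsistent
#' mediation); set `use_abs = FALSE` for the raw comparison. Equal
#' proportions give none.
#'
#' @param fdr_d1,fdr_d2 FDR of the D1 / D2 bootstrap p-values.
#' @param prop_d1,prop_d2 mediation proportions.
#' @param fdr_cut threshold (default 0.05).
#' @param use_abs compare `|proportion|` (default `TRUE`).
#' @return `"D1"`, `"D2"` or `"none"`.
#' @export
classify_direction <- function(fdr_d1, prop_d1, fdr_d2, prop_d2,
                               fdr_cut = 0.05, use_abs = TRUE) {
  p1 <- if (use_abs) abs(prop_d1) else prop_d1
  p2 <- if (use_abs) abs(prop_d2) else prop_d2
  if (is.na(p1) || is.na(p2)) return("none")
  if (!is.na(fdr_d1) && fdr_d1 < fdr_cut && p1 > p2) return("D1")
  if (!is.na(fdr_d2) && fdr_d2 < fdr_cut && p2 > p1) return("D2")
  "none"
}

#' Bidirectional mediation scan over significant exposure-phenotype pairs
#'
#' For each (exposure, phenotype) pair, screens candidate omics features
#' (unless `screen = FALSE`), fits both mediation directions per triple,
#' applies Benjamini-Hochberg separately across all D1 and all D2 bootstrap
#' p-values, and classifies each triple. Deterministic given `seed` (each
#' triple gets a derived child seed, so results do not depend on scan order).
#'
#' @param pairs data frame with columns `exposure`, `phenotype` (names into
#'   the respective tables). An optional `omic` column pins each row to a
#'   single pre-specified triple, bypassing the screen.
#' @param phenotypes,exposures,omics sample-aligned matrices.
#' @param covariates optional covariate data frame; when given, all three
#'   data blocks are residualized on it before screening and fitting.
#' @param n_boot bootstrap draws per fit (default 1000).
#' @param seed integer seed.
#' @param screen apply [screen_candidates()] per pair (default `TRUE`;
#'   `FALSE` uses every omics feature).
#' @param screen_fdr screening threshold (default 0.05).
#' @return data frame of mediation records: one row per triple with both
#'   directions' estimates, FDRs and the assigned `direction`.
#' @export
run_bidirectional_scan <- function(pairs, phenotypes, exposures, omics,
                                   covariates = NULL, n_boot = 1000L,
                                   seed = 1L, screen = TRUE, screen_fdr = 0.05) {
  Y <- as_num_matrix(phenotypes, "phenotypes")
  X <- as_num_matrix(exposures, "exposures")
  O <- as_num_matrix(omics, "omics")
  assert_aligned(Y, X, O)
  if (!is.null(covariates)) {
    Y <- residualize_covariates(Y, covariates)
    X <- residualize_covariates(X, covariates)
    O <- residualize_covariates(O, covariates)
  }
  empty <- data.frame(exposure = character(0), phenotype = character(0),
                      omic = character(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0 || ncol(O) == 0) return(empty)

  rows <- list()
  tri_i <- 0L
  for (i in seq_len(nrow(pairs))) {
    ex <- pairs$exposure[i]; ph <- pairs$phenotype[i]
    xv <- X[, ex]; yv <- Y[, ph]
    cands <- if (!is.null(pairs$omic)) pairs$omic[i]
             else if (screen) screen_candidates(xv, yv, O, fdr = screen_fdr)
             else (colnames(O) %||% seq_len(ncol(O)))
    for (om in cands) {
      tri_i <- tri_i + 1L
      mv <- O[, om]
      d1 <- fit_mediation(xv, mv, yv, n_boot = n_boot,
                          seed = derive_seed(seed, 2L * tri_i))
      d2 <- fit_mediation(xv, yv, mv, n_boot = n_boot,
                          seed = derive_seed(seed, 2L * tri_i + 1L))
      rows[[tri_i]] <- data.frame(
        exposure = ex, phenotype = ph, omic = om,
        acme_d1 = d1$acme, ade_d1 = d1$ade, total_d1 = d1$total,
        prop_d1 = d1$proportion, boot_p_d1 = d1$boot_p,
        ci_lo_d1 = d1$ci[1], ci_hi_d1 = d1$ci[2],
        acme_d2 = d2$acme, ade_d2 = d2$ade, total_d2 = d2$total,
        prop_d2 = d2$proportion, boot_p_d2 = d2$boot_p,
        ci_lo_d2 = d2$ci[1], ci_hi_d2 = d2$ci[2],
        n_used = d1$n_used, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  rec$fdr_d1 <- bh_adjust(rec$boot_p_d1)
  rec$fdr_d2 <- bh_adjust(rec$boot_p_d2)
  rec$direction <- vapply(seq_len(nrow(rec)), function(r) {
    classify_direction(rec$fdr_d1[r], rec$prop_d1[r],
                       rec$fdr_d2[r], rec$prop_d2[r])
  }, character(1))
  rec
}
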