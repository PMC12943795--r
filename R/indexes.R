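# Mediation-weighted omics signature indexes (T-index for transcripts,
# M-index for metabolites/lipids): per-feature weight PropSum_k = sum over
# classified triples of sign(ACME) * mediation proportion; per-sample index
# = sum over features of PropSum_k * normalized feature level.

#' Compute per-feature index weights from classified mediation records
#'
#' For one exposure, every classified triple (direction D1 or D2)
#' contributes `sign(ACME) * proportion` of its assigned direction to the
#' weight of its omics feature; features with no classified triple are
#' absent.
#'
#' @param records mediation record table from [run_bidirectional_scan()].
#' @param exposure exposure name to build the index for.
#' @return list of class `index_weights`: `exposure`, `weights` data frame
#'   (`feature`, `propsum`, `n_triples`), `triples` (feature, phenotype,
#'   proportion, sign, direction).
#' @export
compute_weights <- function(records, exposure) {
  rec <- records[records$exposure == exposure & records$direction != "none", ,
                 drop = FALSE]
  if (nrow(rec) == 0) {
    warning(sprintf("no classified mediation records for exposure '%s'", exposure))
    return(structure(list(exposure = exposure,
                          weights = data.frame(feature = character(0),
                                               propsum = numeric(0),
                                               n_triples = integer(0)),
                          triples = data.frame()),
                     class = "index_weights"))
  }
  acme <- ifelse(rec$direction == "D1", rec$acme_d1, rec$acme_d2)
  prop <- ifelse(rec$direction == "D1", rec$prop_d1, rec$prop_d2)
  sgn <- ifelse(acme < 0, -1, 1)
  triples <- data.frame(feature = rec$omic, phenotype = rec$phenotype,
                        proportion = prop, sign = sgn,
                        direction = rec$direction, stringsAsFactors = FALSE)
  contrib <- triples$sign * triples$proportion
  agg <- stats::aggregate(list(propsum = contrib),
                          by = list(feature = triples$feature), FUN = sum)
  cnt <- stats::aggregate(list(n_triples = contrib),
                          by = list(feature = triples$feature), FUN = length)
  agg$n_triples <- cnt$n_triples[match(agg$feature, cnt$feature)]
  structure(list(exposure = exposure, weights = agg, triples = triples),
            class = "index_weights")
}

#' Compute per-sample index scores
#'
#' Features are mean-imputed and standardized within the cohort, then each
#' sample's index is the weighted sum over the weight features present in
#' the matrix.
#'
#' @param omics samples x features matrix.
#' @param weights an `index_weights` object (or a data frame with columns
#'   `feature`, `propsum`).
#' @param standardize_features standardize features before weighting
#'   (default `TRUE`).
#' @return list of class `index_scores`: `scores` named numeric vector,
#'   `exposure`, `n_features_used`, `overlap_fraction`.
#' @export
compute_index <- function(omics, weights, standardize_features = TRUE) {
  w <- if (inherits(weights, "index_weights")) weights$weights else as.data.frame(weights)
  omics <- as_num_matrix(omics, "omics")
  feats <- intersect(w$feature, colnames(omics))
  if (length(feats) == 0) stop("no overlap between weight features and the omics matrix", call. = FALSE)
  M <- omics[, feats, drop = FALSE]
  for (j in seq_len(ncol(M))) {           # per-feature mean imputation
    miss <- is.na(M[, j])
    if (any(miss)) M[miss, j] <- mean(M[, j], na.rm = TRUE)
  }
  if (standardize_features) {
    sds <- apply(M, 2, stats::sd)
    M <- sweep(sweep(M, 2, colMeans(M), "-"), 2, pmax(sds, .Machine$double.eps), "/")
  }
  wv <- w$propsum[match(feats, w$feature)]
  scores <- as.numeric(M %*% wv)
  names(scores) <- rownames(omics)
  structure(list(scores = scores,
                 exposure = if (inherits(weights, "index_weights")) weights$exposure else NA_character_,
                 n_features_used = length(feats),
                 overlap_fraction = length(feats) / nrow(w)),
            class = "index_scores")
}

#' Regression of an outcome on an index
#'
#' Linear, logistic or multinomial model of the outcome on the index plus
#' covariates (e.g. `outcome ~ index + age + gender`). The multinomial fit
#' maximizes the multinomial-logit likelihood directly via `optim` (BFGS).
#'
#' @param index numeric index scores.
#' @param outcome numeric outcome (linear), binary factor/0-1 (logistic) or
#'   factor with >= 2 levels (multinomial).
#' @param covariates optional covariate data frame.
#' @param family `"linear"`, `"logistic"` or `"multinomial"`.
#' @return for linear/logistic: list `coefficient`, `se`, `p`, `n_used`
#'   (index term). For multinomial: per-level coefficient matrix and
#'   likelihood-ratio p-value for the index.
#' @export
index_outcome_model <- function(index, outcome, covariates = NULL,
                                family = c("linear", "logistic", "multinomial")) {
  family <- match.arg(family)
  cov <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  ok <- !is.na(index) & !is.na(outcome)
  if (!is.null(cov)) ok <- ok & stats::complete.cases(cov)
  df <- data.frame(outcome = outcome[ok], index = index[ok])
  if (!is.null(cov)) df <- cbind(df, cov[ok, , drop = FALSE])
  if (family == "linear") {
    if (stats::sd(df$outcome) == 0) stop("constant outcome", call. = FALSE)
    fit <- stats::lm(outcome ~ ., data = df)
    cf <- stats::summary.lm(fit)$coefficients["index", ]
    return(list(coefficient = cf[[1]], se = cf[[2]], p = floor_p(cf[[4]]),
                n_used = nrow(df), family = family))
  }
  if (family == "logistic") {
    df$outcome <- if (is.factor(outcome)) as.integer(outcome[ok]) - 1L else as.integer(outcome[ok])
    if (length(unique(df$outcome)) < 2) stop("constant outcome", call. = FALSE)
    fit <- stats::glm(outcome ~ ., data = df, family = stats::binomial())
    cf <- summary(fit)$coefficients["index", ]
    return(list(coefficient = cf[[1]], se = cf[[2]], p = floor_p(cf[[4]]),
                n_used = nrow(df), family = family))
  }
  # multinomial logit by direct likelihood maximization
  yf <- factor(outcome[ok])
  if (nlevels(yf) < 2) stop("constant outcome", call. = FALSE)
  X <- stats::model.matrix(~ ., data = df[setdiff(names(df), "outcome")])
  fit_mnl <- function(Xm) {
    K <- nlevels(yf); pX <- ncol(Xm)
    yi <- as.integer(yf)
    nll <- function(par) {
      B <- matrix(par, pX, K - 1)
      eta <- cbind(0, Xm %*% B)
      eta <- eta - apply(eta, 1, max)
      -sum(eta[cbind(seq_along(yi), yi)] - log(rowSums(exp(eta))))
    }
    opt <- stats::optim(rep(0, pX * (K - 1)), nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    list(coef = matrix(opt$par, pX, K - 1,
                       dimnames = list(colnames(Xm), levels(yf)[-1])),
         nll = opt$value)
  }
  full <- fit_mnl(X)
  red <- fit_mnl(X[, setdiff(colnames(X), "index"), drop = FALSE])
  lrt <- 2 * (red$nll - full$nll)
  dfree <- nlevels(yf) - 1
  list(coefficients = full$coef["index", ],
       p = floor_p(stats::pchisq(lrt, dfree, lower.tail = FALSE)),
       n_used = length(yf), family = family)
}

#' Rank-sum comparison of index values between two groups
#'
#' Two-sample, two-sided Wilcoxon rank-sum test; subjects with repeated
#' measures are averaged first.
#'
#' @param index numeric index scores.
#' @param group_labels two-level grouping vector.
#' @param subject optional subject IDs for averaging repeated measures.
#' @return list: `p`, `statistic`, group medians, group sizes.
#' @export
index_group_test <- function(index, group_labels, subject = NULL) {
  if (!is.null(subject)) {
    agg <- stats::aggregate(list(index = index),
                            by = list(subject = subject, group = group_labels),
                            FUN = mean, na.rm = TRUE)
    index <- agg$index
    group_labels <- agg$group
  }
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two non-empty groups required", call. = FALSE)
  a <- index[g == levels(g)[1]]
  b <- index[g == levels(g)[2]]
  if (!length(a) || !length(b)) stop("exactly two non-empty groups required", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       medians = stats::setNames(c(stats::median(a, na.rm = TRUE),
                                   stats::median(b, na.rm = TRUE)), levels(g)),
       n = stats::setNames(c(length(a), length(b)), levels(g)))
}

#' Transfer an index to an external cohort
#'
#' Restricts the frozen weights to the features present in the external
#' matrix (weights are never refitted), standardizes the external features
#' internally, and reports the overlap fraction.
#'
#' @param weights an `index_weights` object.
#' @param external_omics samples x features matrix of the external cohort.
#' @return an `index_scores` object with `overlap_fraction` < 1 when
#'   features are missing.
#' @export
transfer_index <- function(weights, external_omics) {
  compute_index(external_omics, weights, standardize_features = TRUE)
}
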