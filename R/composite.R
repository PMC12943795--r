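# Composite exposures: thresholded Spearman correlation matrix, Ward
# clustering of exposures, one latent variable per cluster from a PLS path
# model (mode A outer, saturated inner, centroid scheme), and the
# uncorrelated-LV stopping rule for the number of clusters.

#' Thresholded Spearman correlation matrix of exposures
#'
#' Pairwise Spearman correlations; entries whose Bonferroni-adjusted p-value
#' (over the `p(p-1)/2` pairs) is >= `alpha_bonf` or whose `|r|` is <=
#' `threshold_r` are set to zero. The diagonal stays 1.
#'
#' @param exposure_table samples x exposures matrix/data frame.
#' @param threshold_r absolute-correlation floor (default 0.2).
#' @param alpha_bonf Bonferroni-adjusted significance threshold (default 0.05).
#' @return list of class `thresholded_correlation`: `r` (thresholded matrix),
#'   `raw_r`, `zeroed` mask, `threshold_r`, `alpha_bonf`.
#' @export
thresholded_spearman <- function(exposure_table, threshold_r = 0.2, alpha_bonf = 0.05) {
  X <- as_num_matrix(as.data.frame(exposure_table), "exposure_table")
  p <- ncol(X)
  r <- stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  n_pair <- crossprod(!is.na(X))
  m <- p * (p - 1) / 2
  # t approximation for the Spearman test, Bonferroni over all pairs
  tstat <- r * sqrt(pmax(n_pair - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), pmax(n_pair - 2, 1), lower.tail = FALSE)
  p_bonf <- pmin(pval * m, 1)
  zero <- (p_bonf >= alpha_bonf) | (abs(r) <= threshold_r)
  diag(zero) <- FALSE
  out <- r
  out[zero] <- 0
  diag(out) <- 1
  structure(list(r = out, raw_r = r, zeroed = zero,
                 threshold_r = threshold_r, alpha_bonf = alpha_bonf),
            class = "thresholded_correlation")
}

#' Ward clustering of exposures on the thresholded correlation matrix
#'
#' Agglomerative Ward (ward.D2) linkage on Euclidean distances between the
#' rows of the thresholded correlation matrix.
#'
#' @param tc a [thresholded_spearman()] result (or a plain correlation matrix).
#' @param k number of clusters, `2 <= k <= p` (k = p gives singletons).
#' @return integer cluster labels named by exposure.
#' @export
ward_cluster <- function(tc, k) {
  r <- if (inherits(tc, "thresholded_correlation")) tc$r else as_num_matrix(tc, "tc")
  p <- nrow(r)
  if (k < 1 || k > p) stop("'k' must lie between 1 and the number of exposures", call. = FALSE)
  hc <- stats::hclust(stats::dist(r), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' PLS path model over exposure clusters
#'
#' One latent variable (LV) per cluster. Outer model is reflective (mode A),
#' the inner model is saturated (every LV pair connected) with the centroid
#' scheme: iterate (1) LV = standardized weighted sum of its block, (2)
#' inner estimate Z_b = LV_b + sum over other blocks of sign(cor) * LV_c,
#' (3) mode A update w_b = cor(X_b, Z_b), until the maximum absolute
#' outer-weight change falls below `tol`. The inner estimate includes the
#' block's own score so that, when a cluster is uncorrelated with every
#' other cluster, the update degrades gracefully to a power iteration and
#' the LV converges to the block's first principal component instead of
#' chasing sampling noise in the other blocks (see the methods vignette).
#' Single-indicator blocks reduce to the standardized indicator; with a
#' single cluster the LV is the block's first principal component. Each LV
#' is oriented to correlate positively with its largest-|loading| exposure.
#'
#' @param exposure_table samples x exposures matrix (complete; impute first).
#' @param clusters integer cluster labels per exposure.
#' @param max_iter maximum iterations (default 300).
#' @param tol convergence tolerance on outer weights (default 1e-6).
#' @return list of class `composite_model`: `k`, `clusters`, `outer_weights`,
#'   `loadings`, `scores` (samples x k, standardized), `iterations`,
#'   `converged`.
#' @export
fit_pls_path <- function(exposure_table, clusters, max_iter = 300L, tol = 1e-6) {
  X <- as_num_matrix(as.data.frame(exposure_table), "exposure_table")
  if (anyNA(X)) stop("PLS path model requires complete data; impute first", call. = FALSE)
  if (length(clusters) != ncol(X))
    stop("'clusters' must label every exposure", call. = FALSE)
  Xs <- standardize(X)
  ks <- sort(unique(clusters))
  k <- length(ks)
  n <- nrow(X)
  blocks <- lapply(ks, function(b) which(clusters == b))
  if (any(lengths(blocks) == 0)) stop("empty cluster", call. = FALSE)

  lv_names <- paste0("LV", seq_len(k))
  scores <- matrix(0, n, k, dimnames = list(rownames(X), lv_names))
  weights <- lapply(blocks, function(ix) rep(1, length(ix)))

  score_of <- function(ix, w) {
    s <- Xs[, ix, drop = FALSE] %*% w
    as.numeric(s) / stats::sd(s)
  }
  for (b in seq_len(k)) scores[, b] <- score_of(blocks[[b]], weights[[b]])

  iterations <- 0L
  converged <- TRUE
  if (k > 1) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      max_delta <- 0
      Cm <- stats::cor(scores)
      for (b in seq_len(k)) {
        e <- sign(Cm[b, -b])
        e[e == 0] <- 1
        Z <- scores[, b] + scores[, -b, drop = FALSE] %*% e
        w_new <- as.numeric(stats::cor(Xs[, blocks[[b]], drop = FALSE], Z))
        # canonicalize sign so the iteration cannot ping-pong
        if (w_new[which.max(abs(w_new))] < 0) w_new <- -w_new
        w_new <- w_new / sqrt(sum(w_new^2))
        w_old <- weights[[b]] / sqrt(sum(weights[[b]]^2))
        max_delta <- max(max_delta, max(abs(w_new - w_old)))
        weights[[b]] <- w_new
        scores[, b] <- score_of(blocks[[b]], w_new)
      }
      iterations <- it
      if (max_delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf("PLS path model did not converge in %d iterations (last change %.3g)",
                   max_iter, max_delta), call. = FALSE)
  } else {
    ix <- blocks[[1]]
    if (length(ix) == 1) {
      weights[[1]] <- 1
      scores[, 1] <- Xs[, ix]
    } else {
      pc <- stats::prcomp(Xs[, ix, drop = FALSE], center = FALSE, scale. = FALSE)
      weights[[1]] <- pc$rotation[, 1]
      scores[, 1] <- score_of(ix, weights[[1]])
    }
  }

  loadings <- vector("list", k)
  for (b in seq_len(k)) {
    ld <- as.numeric(stats::cor(Xs[, blocks[[b]], drop = FALSE], scores[, b]))
    # sign convention: positive correlation with the dominant indicator
    if (ld[which.max(abs(ld))] < 0) {
      weights[[b]] <- -weights[[b]]
      scores[, b] <- -scores[, b]
      ld <- -ld
    }
    names(ld) <- colnames(X)[blocks[[b]]]
    names(weights[[b]]) <- colnames(X)[blocks[[b]]]
    loadings[[b]] <- ld
  }
  scores <- apply(scores, 2, standardize)
  rownames(scores) <- rownames(X)

  structure(list(k = k, clusters = stats::setNames(clusters, colnames(X)),
                 outer_weights = stats::setNames(weights, lv_names),
                 loadings = stats::setNames(loadings, lv_names),
                 scores = scores, iterations = iterations,
                 converged = converged),
            class = "composite_model")
}

#' Select the number of composite exposures
#'
#' Starting at `k_start`, clusters the exposures, fits the PLS path model,
#' and tests all pairwise Spearman correlations among the LV scores; stops at
#' the first k for which no pair is significant at the Bonferroni-adjusted
#' 0.05 level.
#'
#' @param exposure_table samples x exposures matrix (complete).
#' @param k_start first cluster count tried (default 2).
#' @param alpha significance level for LV correlations (default 0.05,
#'   Bonferroni over LV pairs).
#' @param threshold_r,alpha_bonf passed to [thresholded_spearman()].
#' @return list: `k`, `model` (the selected [fit_pls_path()] result),
#'   `trace` data frame (k, max |r|, min adjusted p).
#' @export
select_cluster_count <- function(exposure_table, k_start = 2L, alpha = 0.05,
                                 threshold_r = 0.2, alpha_bonf = 0.05) {
  X <- as_num_matrix(as.data.frame(exposure_table), "exposure_table")
  tc <- thresholded_spearman(X, threshold_r, alpha_bonf)
  p <- ncol(X)
  trace <- data.frame(k = integer(0), max_abs_r = numeric(0), min_p_bonf = numeric(0))
  for (k in seq.int(k_start, p)) {
    cl <- ward_cluster(tc, k)
    model <- fit_pls_path(X, cl)
    S <- model$scores
    m <- choose(k, 2)
    sig <- FALSE
    max_r <- 0; min_p <- 1
    if (m > 0) {
      n <- nrow(S)
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        ct <- suppressWarnings(stats::cor.test(S[, i], S[, j],
                                               method = "spearman", exact = FALSE))
        pb <- min(ct$p.value * m, 1)
        max_r <- max(max_r, abs(ct$estimate))
        min_p <- min(min_p, pb)
        if (pb < alpha) sig <- TRUE
      }
    }
    trace <- rbind(trace, data.frame(k = k, max_abs_r = max_r, min_p_bonf = min_p))
    if (!sig) return(list(k = k, model = model, trace = trace))
  }
  stop("no cluster count up to the number of exposures satisfies the ",
       "uncorrelated-LV rule; consider revising the correlation threshold",
       call. = FALSE)
}

#' EWAS of composite-exposure latent variables
#'
#' Delegates the LV scores as exposures to [run_ewas()].
#'
#' @param model a `composite_model`.
#' @param phenotypes,covariates as in [run_ewas()].
#' @return association table (one row per LV x phenotype).
#' @export
composite_ewas <- function(model, phenotypes, covariates = NULL) {
  if (is.null(model) || model$k == 0)
    return(run_ewas(phenotypes, matrix(numeric(0), nrow(phenotypes), 0), covariates))
  run_ewas(phenotypes, model$scores, covariates)
}
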