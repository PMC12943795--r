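# Distance-matrix variance decomposition of the immunome (PERMANOVA),
# with FDR screening of exposures and redundancy pruning.

#' Pairwise Euclidean distance matrix
#' @param mat samples x features matrix without missing values.
#' @return symmetric n x n distance matrix with sample IDs as dimnames.
#' @export
euclidean_distance <- function(mat) {
  mat <- as_num_matrix(mat, "mat")
  if (anyNA(mat)) stop("distance computation requires complete data", call. = FALSE)
  as.matrix(stats::dist(mat))
}

#' Residualize a feature matrix on covariates
#'
#' Per feature, returns the residuals from a linear model on the covariate
#' design (`~ .` over the covariate data frame). With `covariates = NULL`,
#' features are simply centered.
#'
#' @param mat samples x features matrix.
#' @param covariates data frame of covariates aligned with `mat`, or `NULL`.
#' @return the residualized matrix.
#' @export
residualize_covariates <- function(mat, covariates = NULL) {
  mat <- as_num_matrix(mat, "mat")
  if (is.null(covariates)) return(scale(mat, center = TRUE, scale = FALSE))
  if (nrow(covariates) != nrow(mat))
    stop("covariates must align with the rows of 'mat'", call. = FALSE)
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  out <- mat
  complete_cov <- stats::complete.cases(covariates)
  if (!all(complete_cov)) stop("covariates must be complete", call. = FALSE)
  for (j in seq_len(ncol(mat))) {
    y <- mat[, j]
    ok <- !is.na(y)
    if (all(ok)) {
      out[, j] <- qr.resid(qrX, y)
    } else {
      qr_ok <- qr(X[ok, , drop = FALSE])
      out[ok, j] <- qr.resid(qr_ok, y[ok])
    }
  }
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix over the terms
#' of a design, McArdle-Anderson style: the Gower-centered inner-product
#' matrix `G = -1/2 J D^2 J` is projected through the hat matrices of the
#' sequentially growing model; `R^2 = SS_term / SS_total` and the pseudo-F
#' compares each term's mean square to the residual mean square. P-values
#' come from free permutation of sample labels with the +1 Monte-Carlo
#' correction, or from exhaustive enumeration of all `n!` relabelings when
#' `exact = TRUE` (feasible for n <= 8), in which case
#' `p = #(F* >= F) / n!`.
#'
#' @param dist_matrix n x n distance matrix (or `dist` object).
#' @param design data frame of factors / numeric terms, one column per term,
#'   rows aligned with the distance matrix.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all permutations instead of sampling.
#' @param ss_type `"sequential"` (terms added in the given order) or
#'   `"marginal"`.
#' @return data frame with one row per term plus a residual row: `term`,
#'   `df`, `SS`, `R2`, `pseudo_F`, `p_perm`, `n_perm`.
#' @export
permanova <- function(dist_matrix, design, n_perm = 999L, seed = NULL,
                      exact = FALSE, ss_type = c("sequential", "marginal")) {
  ss_type <- match.arg(ss_type)
  D <- as.matrix(dist_matrix)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0))
    stop("'dist_matrix' must be symmetric with zero diagonal", call. = FALSE)
  if (nrow(design) != n) stop("design rows must align with the distance matrix", call. = FALSE)
  if (!is.null(rownames(D)) && !is.null(rownames(design)) &&
      !identical(rownames(D), rownames(design)))
    stop("sample IDs of design and distance matrix are misaligned", call. = FALSE)
  for (nm in names(design)) {
    v <- design[[nm]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop(sprintf("design term '%s' is constant", nm), call. = FALSE)
  }
  if (anyNA(design)) stop("design must be complete", call. = FALSE)

  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  ss_total <- sum(diag(G))

  terms <- names(design)
  K <- length(terms)
  # hat matrix of intercept + terms 1..j
  hat_of <- function(cols) {
    f <- stats::as.formula(paste("~", paste(cols, collapse = " + ")))
    X <- stats::model.matrix(f, data = design)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  hats <- vector("list", K)
  for (j in seq_len(K)) hats[[j]] <- hat_of(terms[seq_len(j)])
  H_full <- hats[[K]]
  df_model <- sum(diag(H_full)) - 1
  df_res <- n - sum(diag(H_full))
  if (df_res <= 0) stop("design leaves no residual degrees of freedom", call. = FALSE)

  stats_for <- function(Gp) {
    tr <- function(H) sum(H * Gp)   # tr(H G) for symmetric H, G
    ss_res <- sum(diag(Gp)) - tr(H_full)
    ss <- df <- numeric(K)
    prev_tr <- 0
    prev_df <- 1
    for (j in seq_len(K)) {
      tj <- tr(hats[[j]])
      dj <- sum(diag(hats[[j]]))
      if (ss_type == "sequential" || j == 1) {
        ss[j] <- tj - prev_tr
        df[j] <- dj - prev_df
      }
      prev_tr <- tj
      prev_df <- dj
    }
    if (ss_type == "marginal" && K > 1) {
      t_full <- tr(H_full)
      d_full <- sum(diag(H_full))
      for (j in seq_len(K)) {
        Hm <- hat_of(terms[-j])
        ss[j] <- t_full - tr(Hm)
        df[j] <- d_full - sum(diag(Hm))
      }
    }
    Fv <- (ss / df) / (ss_res / df_res)
    list(ss = ss, df = df, F = Fv, ss_res = ss_res)
  }

  obs <- stats_for(G)

  if (exact) {
    perms <- all_permutations(n)
    n_used <- nrow(perms)
    count_ge <- numeric(K)
    for (i in seq_len(n_used)) {
      p <- perms[i, ]
      Fp <- stats_for(G[p, p])$F
      count_ge <- count_ge + (Fp >= obs$F - 1e-12)
    }
    p_perm <- count_ge / n_used
  } else {
    if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    n_used <- n_perm
    count_ge <- numeric(K)
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      Fp <- stats_for(G[p, p])$F
      count_ge <- count_ge + (Fp >= obs$F - 1e-12)
    }
    p_perm <- (1 + count_ge) / (1 + n_perm)
  }

  data.frame(
    term = c(terms, "residual"),
    df = c(obs$df, df_res),
    SS = c(obs$ss, obs$ss_res),
    R2 = c(obs$ss, obs$ss_res) / ss_total,
    pseudo_F = c(obs$F, NA_real_),
    p_perm = c(p_perm, NA_real_),
    n_perm = c(rep(n_used, K), NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Single-exposure PERMANOVA screen
#'
#' Runs a one-term PERMANOVA per exposure against the same distance matrix.
#'
#' @param dist_matrix n x n distance matrix.
#' @param exposure_table samples x exposures matrix/data frame; exposures
#'   with missing values are fitted on complete cases of the full index
#'   (missing rows dropped per exposure by re-deriving the distance matrix is
#'   out of scope: exposures here are assumed imputed upstream).
#' @param n_perm permutations per exposure (default 999).
#' @param seed integer seed.
#' @return data frame: exposure, df, SS, R2, pseudo_F, p_perm.
#' @export
permanova_screen <- function(dist_matrix, exposure_table, n_perm = 999L, seed = NULL) {
  X <- as.data.frame(exposure_table)
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    res <- permanova(dist_matrix, X[j], n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, j))
    out[[j]] <- res[1, c("df", "SS", "R2", "pseudo_F", "p_perm")]
  }
  cbind(data.frame(exposure = names(X), stringsAsFactors = FALSE),
        do.call(rbind, out))
}

#' FDR screening and redundancy pruning of exposures
#'
#' Benjamini-Hochberg over the permutation p-values; among survivors, builds
#' a graph with an edge wherever `|Spearman r| > r_cut` and keeps, per
#' connected component, the exposure with the largest PERMANOVA `R^2`.
#'
#' @param components data frame from [permanova_screen()] (needs columns
#'   `exposure`, `R2`, `p_perm`).
#' @param exposure_table samples x exposures table used for the Spearman
#'   correlations.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param r_cut absolute Spearman correlation defining redundancy (default 0.4).
#' @return list with `representatives` (character vector) and the annotated
#'   `table` (columns `fdr`, `kept`).
#' @export
screen_and_prune <- function(components, exposure_table, fdr_cut = 0.05, r_cut = 0.4) {
  components$fdr <- bh_adjust(components$p_perm)
  surv <- components[components$fdr < fdr_cut, , drop = FALSE]
  components$kept <- FALSE
  if (nrow(surv) == 0)
    return(list(representatives = character(0), table = components))
  X <- as_num_matrix(as.data.frame(exposure_table)[surv$exposure], "exposure_table")
  r <- stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  m <- nrow(surv)
  # union-find over |r| > r_cut edges
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (!is.na(r[i, j]) && abs(r[i, j]) > r_cut) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  reps <- character(0)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    best <- members[which.max(surv$R2[members])]
    reps <- c(reps, surv$exposure[best])
  }
  components$kept <- components$exposure %in% reps
  list(representatives = reps, table = components)
}
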