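# Shared fixtures, all generated in code.

# small covariate frame for association tests
make_covars <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 20, 60),
             gender = factor(sample(c("female", "male"), n, replace = TRUE)),
             month = sample(1:12, n, replace = TRUE),
             row.names = sprintf("S%05d", seq_len(n)))
}

# exposures with `n_blocks` latent-factor blocks of `block_size`, rest noise
make_block_exposures <- function(n, n_blocks = 3, block_size = 5, r = 0.6,
                                 n_noise = 0, seed = 1) {
  set.seed(seed)
  p <- n_blocks * block_size + n_noise
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%05d", seq_len(n)), paste0("e", seq_len(p))))
  f <- matrix(rnorm(n * n_blocks), n, n_blocks)
  for (b in seq_len(n_blocks)) {
    ix <- ((b - 1) * block_size + 1):(b * block_size)
    X[, ix] <- sqrt(r) * f[, b] + sqrt(1 - r) * X[, ix]
  }
  list(X = X, factors = f, labels = rep(seq_len(n_blocks), each = block_size))
}

# adjusted Rand index (direct contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# brute-force PERMANOVA oracle for a one-factor two-group design:
# classic sums-of-squared-distances formulas plus exhaustive enumeration of
# all distinct balanced assignments (independent of the hat-matrix path)
permanova_oracle <- function(D, groups) {
  f_of <- function(g) {
    n <- nrow(D)
    levs <- unique(g)
    ss_total <- sum(D[upper.tri(D)]^2) / n
    ss_within <- 0
    for (l in levs) {
      ix <- which(g == l)
      if (length(ix) > 1) {
        sub <- D[ix, ix]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(ix)
      }
    }
    ss_between <- ss_total - ss_within
    a <- length(levs)
    (ss_between / (a - 1)) / (ss_within / (n - a))
  }
  n <- nrow(D)
  n1 <- sum(groups == unique(groups)[1])
  f_obs <- f_of(groups)
  combos <- utils::combn(n, n1)
  fs <- apply(combos, 2, function(ix) {
    g <- rep("B", n); g[ix] <- "A"
    f_of(g)
  })
  list(F = f_obs, p = mean(fs >= f_obs - 1e-12))
}
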