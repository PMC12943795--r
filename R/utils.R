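# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_aligned <- function(...) {
  tabs <- list(...)
  ids <- lapply(tabs, rownames)
  ref <- ids[[1L]]
  if (is.null(ref)) stop("tables must carry sample IDs as row names", call. = FALSE)
  for (i in seq_along(ids)[-1L]) {
    if (!identical(ids[[i]], ref)) {
      stop("sample IDs are not aligned across tables", call. = FALSE)
    }
  }
  invisible(ref)
}

as_num_matrix <- function(x, what = "matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix or data frame", what), call. = FALSE)
  }
  x
}

# p-value floor: avoids -log10 underflow downstream
P_FLOOR <- 1e-300

floor_p <- function(p) pmax(p, P_FLOOR)

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment. Thin, named wrapper so every
#' module applies the identical procedure; `NA` entries are preserved.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values (FDR), same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# Derive a per-stage / per-unit child seed from a user seed, staying < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(index)) %% 2147483647) + 1L
}

# Deterministic permutations of 1:n (lexicographic); n <= 8 keeps this small.
all_permutations <- function(n) {
  if (n > 9) stop("exhaustive enumeration limited to n <= 9", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}
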