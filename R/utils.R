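# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never disturbs user-level RNG.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Upper-triangle values of a symmetric matrix (excluding the diagonal).
upper_tri_values <- function(m) m[upper.tri(m)]

# Index pairs (i < j) of the upper triangle, as a 2-column matrix.
upper_tri_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  which(upper.tri(diag(n)), arr.ind = TRUE)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}
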