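# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# All unordered pairs (i < j) among `idx`, as a 2-column integer matrix.
pairs_within <- function(idx) {
  idx <- sort(as.integer(idx))
  n <- length(idx)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cmb <- utils::combn(idx, 2L)
  cbind(cmb[1L, ], cmb[2L, ])
}

# All unordered pairs between two disjoint index sets, normalized to i < j.
pairs_between <- function(idx_a, idx_b) {
  g <- expand.grid(a = as.integer(idx_a), b = as.integer(idx_b))
  cbind(pmin(g$a, g$b), pmax(g$a, g$b))
}

# Encode unordered pairs as single integers for fast set algebra.
pair_key <- function(pairs, m) {
  if (nrow(pairs) == 0L) return(integer(0))
  (pairs[, 1L] - 1L) * m + pairs[, 2L]
}

upper_entries <- function(M, diag = FALSE) {
  M[upper.tri(M, diag = diag)]
}
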