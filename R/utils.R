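# shared internal helpers

check_row_stochastic <- function(m, name, tol = 1e-12) {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (any(m < 0 | m > 1)) {
    abort(sprintf("`%s` has entries outside [0, 1].", name))
  }
  bad <- which(abs(rowSums(m) - 1) > tol)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` is not row-stochastic: row %d sums to %.15g (must be 1).",
      name, bad[1], rowSums(m)[bad[1]]
    ))
  }
  invisible(m)
}

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(p)
}

# Categorical draws, one per row of a probability matrix.
sample_rows <- function(prob, u = runif(nrow(prob))) {
  k <- ncol(prob)
  if (k == 1) return(rep(1L, nrow(prob)))
  cum <- prob
  for (j in 2:k) cum[, j] <- cum[, j - 1] + cum[, j]
  1L + rowSums(cum < u * cum[, k])
}

sample_categorical <- function(p) {
  sample.int(length(p), 1L, prob = p)
}

# Derive a reproducible 32-bit sub-seed from a root seed and a stream label.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i)) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x) && x >= 1
}
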