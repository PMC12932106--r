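# Independent oracles used across tests; deliberately naive implementations
# that share no code with the package internals they check.

# exhaustive D-optimal subset search over all C(m, n) designs
brute_force_doptimal <- function(points, n_runs) {
  X <- aavdoe::scheffe_matrix(points)
  combos <- utils::combn(nrow(points), n_runs)
  best <- -Inf
  for (j in seq_len(ncol(combos))) {
    M <- crossprod(X[combos[, j], , drop = FALSE])
    d <- det(M)
    val <- if (d > 0) log(d) else -Inf
    if (val > best) best <- val
  }
  best
}

# term-by-term Scheffe polynomial evaluation
eval_scheffe_manual <- function(beta, x) {
  x1 <- x[, 1]; x2 <- x[, 2]; x3 <- x[, 3]
  beta[1] * x1 + beta[2] * x2 + beta[3] * x3 +
    beta[4] * x1 * x2 + beta[5] * x1 * x3 + beta[6] * x2 * x3
}

# term-by-term second-order polynomial evaluation (2 coded factors)
eval_rsm_manual <- function(beta, z) {
  z1 <- z[, 1]; z2 <- z[, 2]
  beta[1] + beta[2] * z1 + beta[3] * z2 +
    beta[4] * z1^2 + beta[5] * z2^2 + beta[6] * z1 * z2
}

# minimal design object holding arbitrary composition rows
as_mixture_design <- function(runs) {
  runs <- as.matrix(runs)
  colnames(runs) <- c("pHelper", "pRepCap", "pGOI")
  structure(list(runs = runs, criterion_value = NA_real_),
            class = "mixture_design")
}

random_feasible_bounds <- function() {
  repeat {
    lo <- runif(3, 0, 0.25)
    hi <- lo + runif(3, 0.2, 0.6)
    hi <- pmin(hi, 1)
    ok <- tryCatch({
      aavdoe::mixture_bounds(lo, hi)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(aavdoe::mixture_bounds(lo, hi))
  }
}
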