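# Small dataset builders shared across tests.

# A quick individual-level dataset with a couple of strong causal SNPs.
quick_dataset <- function(n = 300, J = 60, R = 3, n_causal = 2, pve = 0.1,
                          seed = 1, ...) {
  simulate_dataset(sim_scenario(n = n, J = J, R = R, n_causal = n_causal,
                                pve = pve, seed = seed, ...))
}

# Random marginal statistics for SER-level tests.
random_marginal_stats <- function(J = 4, R = 2, seed = 1, xtx_const = TRUE) {
  set.seed(seed)
  A <- matrix(rnorm(R * R), R)
  V <- crossprod(A) + diag(R)
  xtx <- if (xtx_const) rep(50, J) else runif(J, 20, 100)
  bhat <- matrix(rnorm(J * R, sd = 0.3), J, R)
  marginal_stats(bhat, xtx, V)
}

# A small random PSD matrix.
random_psd <- function(R, seed = 1, singular = FALSE) {
  set.seed(seed)
  if (singular) {
    v <- matrix(rnorm(R), R, 1)
    tcrossprod(v)
  } else {
    A <- matrix(rnorm(R * R), R)
    crossprod(A) + 0.1 * diag(R)
  }
}
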