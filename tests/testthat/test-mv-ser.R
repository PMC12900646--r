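test_that("component_log_bf matches scalar closed forms and null cases", {
  # zero prior component: BF = 1, posterior degenerate at zero
  r <- component_log_bf(c(0.5, -1), diag(2), matrix(0, 2, 2))
  expect_equal(r$lbf, 0)
  expect_equal(r$mu1, c(0, 0))
  expect_equal(r$Sigma1, matrix(0, 2, 2))
  # scalar conjugate normal: S = 1, U = 1, bhat = 2
  r <- component_log_bf(2, matrix(1), matrix(1))
  expect_equal(r$lbf, dnorm(2, 0, sqrt(2), log = TRUE) -
                 dnorm(2, 0, 1, log = TRUE), tolerance = 1e-12)
  expect_equal(drop(r$mu1), 1, tolerance = 1e-12)
  expect_equal(drop(r$Sigma1), 0.5, tolerance = 1e-12)
  expect_error(component_log_bf(c(1, 1), matrix(0, 2, 2), diag(2)),
               "positive definite")
  expect_error(component_log_bf(c(NA, 1), diag(2), diag(2)), "non-finite")
})

test_that("component_log_bf agrees with importance sampling, incl. singular U", {
  cases <- list(
    list(R = 2, singular = FALSE, seed = 1),
    list(R = 2, singular = TRUE, seed = 2),
    list(R = 3, singular = FALSE, seed = 3),
    list(R = 3, singular = TRUE, seed = 4))
  for (cs in cases) {
    set.seed(cs$seed)
    S <- random_psd(cs$R, seed = cs$seed + 10)
    U <- if (cs$singular) matrix(1, cs$R, cs$R) else
      random_psd(cs$R, seed = cs$seed + 20)
    bhat <- rnorm(cs$R)
    r <- component_log_bf(bhat, S, U)
    o <- oracle_is_moments(bhat, S, U, ndraw = 2e5, seed = cs$seed)
    expect_equal(r$lbf, o$lbf, tolerance = 0.02)
    expect_equal(r$mu1, o$mu1, tolerance = 0.02 * max(1, max(abs(o$mu1))))
  }
})

test_that("logBF is invariant under joint rescaling of bhat, S, U", {
  set.seed(8)
  S <- random_psd(3, 1); U <- random_psd(3, 2); b <- rnorm(3)
  r1 <- component_log_bf(b, S, U)
  r2 <- component_log_bf(10 * b, 100 * S, 100 * U)
  expect_equal(r1$lbf, r2$lbf, tolerance = 1e-9)
})

test_that("posterior mean shrinks toward zero when U is proportional to S", {
  set.seed(9)
  S <- random_psd(3, 5)
  b <- rnorm(3)
  Sinv <- solve(S)
  for (c0 in c(0.5, 1, 4)) {
    r <- component_log_bf(b, S, c0 * S)
    # closed form: mu1 = c0/(1+c0) * bhat
    expect_equal(r$mu1, c0 / (1 + c0) * b, tolerance = 1e-10)
    expect_lte(drop(t(r$mu1) %*% Sinv %*% r$mu1),
               drop(t(b) %*% Sinv %*% b))
  }
})

test_that("ser_fit matches brute-force enumeration on toy instances", {
  for (seed in 1:5) {
    J <- sample(2:5, 1)
    R <- sample(2:3, 1)
    ms <- random_marginal_stats(J = J, R = R, seed = seed,
                                xtx_const = seed %% 2 == 0)
    Ulist <- list(random_psd(R, seed, singular = TRUE),
                  random_psd(R, seed + 1),
                  diag(R))
    prior <- mix_prior(Ulist, weights = c(0.5, 0.3, 0.2))
    fit <- ser_fit(ms, prior, sigma2_0 = 0.8)
    o <- oracle_ser(ms$bhat, ms$xtx, ms$V, Ulist, prior$w, sigma2 = 0.8)
    expect_equal(fit$alpha, o$alpha, tolerance = 1e-10)
    expect_equal(fit$lbf_model, o$lbf_model, tolerance = 1e-10)
    expect_equal(fit$comp_post, o$comp_post, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sum(fit$alpha), 1, tolerance = 1e-12)
    expect_equal(rowSums(fit$comp_post), rep(1, J), tolerance = 1e-12)
  }
})

test_that("ser_fit handles symmetry and degenerate cases", {
  # identical SNPs: alpha uniform by symmetry
  V <- diag(2)
  bhat <- matrix(rep(c(0.4, 0.2), each = 3), 3, 2)
  ms <- marginal_stats(bhat, rep(50, 3), V)
  fit <- ser_fit(ms, mix_prior(canonical_components(2)))
  expect_equal(fit$alpha, rep(1 / 3, 3), tolerance = 1e-12)
  # J = 1: certainty regardless of data
  ms1 <- marginal_stats(matrix(c(0.1, -0.2), 1, 2), 5, V)
  expect_equal(ser_fit(ms1, mix_prior(canonical_components(2)))$alpha, 1)
  # sigma2_0 = 0: null model, uniform alpha, zero moments
  fit0 <- ser_fit(ms, mix_prior(canonical_components(2)), sigma2_0 = 0)
  expect_equal(fit0$lbf_model, 0)
  expect_equal(fit0$bbar, matrix(0, 3, 2))
})

test_that("lfsr conventions: symmetric, point-mass-zero, and tail cases", {
  V <- diag(2)
  # posterior symmetric around zero: bhat = 0 gives lfsr = 0.5
  ms <- marginal_stats(matrix(0, 2, 2), rep(10, 2), V)
  prior <- mix_prior(list(diag(2)))
  lf <- ser_lfsr(ser_fit(ms, prior))
  expect_equal(unname(lf$snp), matrix(0.5, 2, 2), tolerance = 1e-12)
  # all mass on a trait-1-only component: trait 2 has lfsr = 1
  prior1 <- mix_prior(list(matrix(c(1, 0, 0, 0), 2, 2)))
  ms2 <- marginal_stats(matrix(c(2, 2, 0, 0), 2, 2), rep(100, 2), V)
  lf2 <- ser_lfsr(ser_fit(ms2, prior1))
  expect_true(all(lf2$snp[, 2] == 1))
  expect_equal(lf2$effect[2], 1)
  expect_lt(lf2$effect[1], 0.01)  # strong positive effect on trait 1
  # direct definition check: P(b > 0) = 0.99 gives lfsr = 0.01
  mu <- qnorm(0.99)  # N(mu, 1): P(b > 0) = 0.99
  expect_equal(1 - pnorm(0, mu, 1, lower.tail = FALSE), 0.01,
               tolerance = 1e-12)
  expect_true(all(lf2$snp >= 0 & lf2$snp <= 1))
})

test_that("estimate_prior_scale: ascent, grid agreement, null behavior", {
  set.seed(10)
  # single-component scalar prior: maximizer matches a dense grid search
  J <- 30
  bhat <- matrix(rnorm(J, sd = 0.5), J, 1)
  ms <- marginal_stats(bhat, rep(40, J), matrix(1))
  prior <- mix_prior(list(matrix(1)))
  grid <- 10^seq(-6, 2, length.out = 2000)
  lbfs <- vapply(grid, function(s2)
    mvfine:::ser_lbf_model(ms, prior, rep(1 / J, J), s2), 0)
  s2_grid <- grid[which.max(lbfs)]
  s2_opt <- estimate_prior_scale(ms, prior, sigma2_0 = 1)
  if (max(lbfs) > 0) {
    expect_equal(log(s2_opt), log(s2_grid), tolerance = 0.02)
  } else {
    expect_equal(s2_opt, 0)
  }
  # ascent property for both methods
  for (m in c("optim", "EM")) {
    s2_new <- estimate_prior_scale(ms, prior, sigma2_0 = 0.5, method = m)
    lbf_new <- if (s2_new > 0)
      mvfine:::ser_lbf_model(ms, prior, rep(1 / J, J), s2_new) else 0
    lbf_old <- mvfine:::ser_lbf_model(ms, prior, rep(1 / J, J), 0.5)
    expect_gte(lbf_new, lbf_old - 1e-10)
  }
})

test_that("null residuals drive the prior scale to zero", {
  set.seed(11)
  n <- 2000; J <- 40
  # bhat consistent with pure noise at large n
  bhat <- matrix(rnorm(J, sd = sqrt(1 / n)), J, 1)
  ms <- marginal_stats(bhat, rep(n, J), matrix(1))
  prior <- mix_prior(list(matrix(1)))
  expect_equal(estimate_prior_scale(ms, prior, sigma2_0 = 1), 0)
  expect_equal(estimate_prior_scale(ms, prior, sigma2_0 = 1, method = "EM"), 0)
})
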