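test_that("center_and_standardize centers, scales, drops monomorphic columns", {
  set.seed(1)
  X <- cbind(rbinom(50, 2, 0.3), rep(2, 50), rbinom(50, 2, 0.4))
  Y <- matrix(rnorm(100), 50, 2)
  expect_warning(cs <- center_and_standardize(X, Y), "monomorphic")
  expect_equal(ncol(cs$X), 2)
  expect_equal(cs$kept, c(1L, 3L))
  expect_lt(max(abs(colMeans(cs$X))), 1e-10)
  expect_lt(max(abs(colMeans(cs$Y))), 1e-10)
  expect_equal(apply(cs$X, 2, sd), rep(1, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # idempotence on already-centered input
  cs2 <- center_and_standardize(cs$X, cs$Y)
  expect_equal(unclass(cs2$X), unclass(cs$X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(center_and_standardize(X[1, , drop = FALSE],
                                      Y[1, , drop = FALSE]), "2 samples")
})

test_that("sufficient statistics are exact products and round-trip the fit", {
  dat <- quick_dataset(n = 200, J = 30, R = 2, seed = 5)
  cs <- center_and_standardize(dat$X, dat$Y)
  st <- compute_sufficient_stats(cs$X, cs$Y)
  expect_equal(st$XtX, crossprod(cs$X), ignore_attr = TRUE)
  expect_equal(st$XtY, crossprod(cs$X, cs$Y), ignore_attr = TRUE)
  expect_equal(diag(st$XtX), rep(nrow(cs$X) - 1, ncol(cs$X)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # fitting from (X, Y) equals fitting from the sufficient statistics
  prior <- mix_prior(canonical_components(2))
  V <- cov(cs$Y)
  f1 <- mvfine(dat$X, dat$Y, prior = prior, V = V,
               opts = fit_options(L = 3))
  f2 <- ibss(st, prior, V = V, opts = fit_options(L = 3))
  expect_identical(f1$pip, f2$pip)
  expect_identical(f1$elbo, f2$elbo)
})

test_that("a single strong causal SNP yields one active, concentrated effect", {
  dat <- quick_dataset(n = 800, J = 100, R = 3, n_causal = 1, pve = 0.15,
                       seed = 42)
  fit <- mvfine(dat$X, dat$Y, prior = scenario_prior(dat$scenario),
                V = dat$V_true, opts = fit_options(L = 10))
  expect_length(fit$active_effects, 1)
  l <- fit$active_effects
  expect_gt(sum(fit$sers[[l]]$alpha[dat$causal]), 0.5)
  expect_gt(max(fit$pip[dat$causal]), 0.5)
})

test_that("null data prunes all effects and yields no credible sets", {
  set.seed(13)
  n <- 500; J <- 80; R <- 3
  X <- simulate_genotypes(n, J, seed = 99)$X
  Y <- matrix(rnorm(n * R), n, R)
  fit <- mvfine(X, Y, prior = mix_prior(canonical_components(R)),
                opts = fit_options(L = 10))
  expect_length(fit$active_effects, 0)
  expect_length(fit$cs, 0)
  expect_equal(fit$pip, rep(0, J))
})

test_that("ELBO is monotone and tight at L = 1", {
  for (seed in 1:5) {
    dat <- quick_dataset(n = 150, J = 20, R = 2, seed = seed)
    cs <- center_and_standardize(dat$X, dat$Y)
    st <- compute_sufficient_stats(cs$X, cs$Y)
    V <- cov(cs$Y)
    prior <- mix_prior(canonical_components(2))
    fit <- ibss(st, prior, V = V,
                opts = fit_options(L = 4, tol = 1e-8, max_iter = 100))
    expect_true(all(diff(fit$elbo) > -1e-6))
    # L = 1, fixed scale: ELBO equals the exact log evidence
    fit1 <- ibss(st, prior, V = V,
                 opts = fit_options(L = 1, estimate_prior_scale = FALSE))
    Vinv <- chol2inv(chol(V))
    null_ll <- -0.5 * st$n * st$R * log(2 * pi) -
      0.5 * st$n * as.numeric(determinant(V)$modulus) -
      0.5 * sum(Vinv * st$YtY)
    expect_equal(tail(fit1$elbo, 1),
                 null_ll + fit1$sers[[1]]$lbf_model, tolerance = 1e-8)
  }
})

test_that("L = 1 alpha equals enumeration over the single causal SNP", {
  # exactness of the variational fit at L = 1: compare against direct
  # evaluation of the nR-dimensional marginal density per (SNP, component)
  for (seed in 1:3) {
    set.seed(seed)
    n <- 25; J <- 4; R <- 2
    X <- matrix(rnorm(n * J), n, J)
    B <- matrix(0, J, R); B[2, ] <- c(0.6, 0.3)
    Y <- X %*% B + matrix(rnorm(n * R, sd = 0.8), n, R)
    cs <- center_and_standardize(X, Y)
    st <- compute_sufficient_stats(cs$X, cs$Y)
    V <- 0.64 * diag(R)
    Ulist <- list(random_psd(R, seed), matrix(1, R, R))
    prior <- mix_prior(Ulist, weights = c(0.6, 0.4))
    fit <- ibss(st, prior, V = V,
                opts = fit_options(L = 1, estimate_prior_scale = FALSE))
    o <- oracle_enum_single_causal(cs$X, cs$Y, V, Ulist, prior$w)
    expect_equal(fit$sers[[1]]$alpha, o$alpha, tolerance = 1e-10)
    # the ELBO is a lower bound on (here: equals) the exact evidence
    expect_lte(tail(fit$elbo, 1), o$log_evidence + 1e-6)
  }
})

test_that("SNP permutation permutes outputs identically", {
  dat <- quick_dataset(n = 300, J = 40, R = 2, seed = 21)
  prior <- mix_prior(canonical_components(2))
  V <- cov(scale(dat$Y, scale = FALSE))
  set.seed(1)
  perm <- sample(ncol(dat$X))
  f1 <- mvfine(dat$X, dat$Y, prior = prior, V = V, opts = fit_options(L = 3))
  f2 <- mvfine(dat$X[, perm], dat$Y, prior = prior, V = V,
               opts = fit_options(L = 3))
  expect_equal(f2$pip[order(perm)], f1$pip, tolerance = 1e-9)
})

test_that("duplicated causal column splits alpha but keeps CS-level recovery", {
  dat <- quick_dataset(n = 600, J = 50, R = 2, n_causal = 1, pve = 0.15,
                       seed = 33)
  j <- dat$causal
  Xdup <- cbind(dat$X, dat$X[, j])
  fit <- mvfine(Xdup, dat$Y, prior = scenario_prior(dat$scenario),
                V = dat$V_true, opts = fit_options(L = 3))
  Jd <- ncol(Xdup)
  l <- fit$active_effects[1]
  a <- fit$sers[[l]]$alpha
  # the two copies share the alpha mass roughly equally
  expect_gt(a[j] + a[Jd], 0.5)
  expect_lt(abs(a[j] - a[Jd]), 0.2)
  # and the credible set contains at least one copy
  expect_true(any(c(j, Jd) %in% unlist(lapply(fit$cs, `[[`, "members"))))
})

test_that("degenerate J = 1 input returns a certain single effect", {
  set.seed(3)
  X <- matrix(rbinom(100, 2, 0.4), 100, 1)
  Y <- matrix(0.5 * scale(X) + rnorm(100), 100, 1)
  fit <- mvfine(X, Y, prior = mix_prior(list(matrix(1))),
                opts = fit_options(L = 2))
  expect_equal(fit$sers[[1]]$alpha, 1)
  expect_equal(fit$pip, 1)
})

test_that("get_elbo on a returned fit reproduces the final trace value", {
  dat <- quick_dataset(n = 200, J = 30, R = 2, seed = 8)
  cs <- center_and_standardize(dat$X, dat$Y)
  st <- compute_sufficient_stats(cs$X, cs$Y)
  V <- cov(cs$Y)
  fit <- ibss(st, mix_prior(canonical_components(2)), V = V,
              opts = fit_options(L = 3))
  expect_equal(get_elbo(st, fit), tail(fit$elbo, 1), tolerance = 1e-9)
})
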