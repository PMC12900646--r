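test_that("genotype simulation: determinism, moments, LD structure", {
  g1 <- simulate_genotypes(2000, 60, ld_rho = 0, seed = 3)
  g2 <- simulate_genotypes(2000, 60, ld_rho = 0, seed = 3)
  expect_identical(g1$X, g2$X)
  expect_true(all(g1$X %in% 0:2))
  # dosage means near 2 * MAF
  expect_lt(max(abs(colMeans(g1$X) - 2 * g1$maf)), 4 * sqrt(0.5 / 2000) + 0.05)
  # ld_rho = 0: off-diagonal LD is sampling noise
  ld0 <- cor(g1$X)
  expect_lt(mean(abs(ld0[upper.tri(ld0)])), 0.05)
  # strong within-block LD when ld_rho is high, none across blocks
  g3 <- simulate_genotypes(3000, 40, ld_block_size = 20, ld_rho = 0.95,
                           seed = 4)
  ld3 <- cor(g3$X)
  # thresholding the latent Gaussian attenuates LD relative to ld_rho, but
  # adjacent within-block dosage correlation stays far above the
  # across-block (independent) level
  within <- mean(abs(ld3[cbind(1:19, 2:20)]))
  across <- mean(abs(ld3[1:20, 21:40]))
  expect_gt(within, 0.25)
  expect_lt(across, 0.1)
})

test_that("effect simulation honors the sharing patterns", {
  sc <- sim_scenario(J = 50, R = 4, n_causal = 3,
                     sharing_spec = c(trait_specific = 1), seed = 5)
  ef <- simulate_effects(sc)
  expect_length(ef$causal, 3)
  for (j in ef$causal)
    expect_equal(sum(ef$B[j, ] != 0), 1)
  expect_true(all(ef$B[-ef$causal, ] == 0))
  # equal effects on a pair
  sc2 <- sim_scenario(J = 50, R = 4, n_causal = 2,
                      sharing_spec = c(equal_pair = 1), seed = 6)
  ef2 <- simulate_effects(sc2)
  for (j in ef2$causal) {
    nz <- ef2$B[j, ef2$B[j, ] != 0]
    expect_length(nz, 2)
    expect_equal(nz[1], nz[2])
  }
  # draws from a singular supplied component lie in its column space
  U <- tcrossprod(c(1, 2, 0, -1))
  sc3 <- sim_scenario(J = 20, R = 4, n_causal = 2, components = list(U),
                      seed = 7)
  ef3 <- simulate_effects(sc3)
  for (j in ef3$causal) {
    b <- ef3$B[j, ]
    expect_equal(b / b[1], c(1, 2, 0, -1), tolerance = 1e-10)
  }
  expect_error(simulate_effects(sim_scenario(J = 4, n_causal = 5, R = 2)),
               "n_causal")
})

test_that("trait simulation hits the pve target and respects trait_corr", {
  sc <- sim_scenario(n = 2000, J = 60, R = 3, n_causal = 2, pve = 0.08,
                     trait_corr = 0.4, seed = 8)
  dat <- simulate_dataset(sc)
  vg <- apply(dat$X %*% dat$B_true, 2, var)
  signal <- vg > 0
  realized <- vg[signal] / (vg[signal] + diag(dat$V_true)[signal])
  expect_equal(realized, rep(0.08, sum(signal)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # pve = 0 route: pure correlated noise
  tr <- simulate_traits(dat$X, matrix(0, 60, 3), dat$scenario$trait_corr,
                        pve = 0, seed = 9)
  expect_equal(cor(tr$Y)[1, 2], 0.4, tolerance = 0.08)
  # rescaling invariance: doubling B before the call changes nothing
  tr1 <- simulate_traits(dat$X, dat$B_true, dat$V_true, 0.05, seed = 10)
  tr2 <- simulate_traits(dat$X, 2 * dat$B_true, dat$V_true, 0.05, seed = 10)
  expect_identical(tr1$Y, tr2$Y)
})

test_that("dataset simulation is byte-identical given the scenario", {
  sc <- sim_scenario(n = 100, J = 30, R = 2, seed = 77)
  d1 <- simulate_dataset(sc)
  d2 <- simulate_dataset(sc)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$Y, d2$Y)
  expect_identical(d1$B_true, d2$B_true)
})

test_that("evaluation metrics implement the printed formulas", {
  # hand-built contingency: TP = 3, FP = 1, FN = 1
  expect_equal(fdr_power(3, 1, 1), list(fdr = 0.25, power = 0.75))
  expect_equal(fdr_power(0, 0, 2), list(fdr = NA_real_, power = 0))
  B <- matrix(0, 10, 2)
  B[c(2, 5, 7, 9), 1] <- 1
  pip <- rep(0, 10); pip[c(2, 5, 7)] <- 0.99; pip[3] <- 0.99
  cs <- list(list(members = c(2)), list(members = c(5, 6)),
             list(members = c(3)))
  for (i in seq_along(cs)) cs[[i]]$purity <- 1
  fit <- list(pip = pip, cs = cs, lfsr_snp = NULL)
  ev <- evaluate_finemap(fit, list(B_true = B))
  # at threshold 0.5: calls {2,5,7,3}; causal {2,5,7,9}
  row <- ev$pip_curve[ev$pip_curve$threshold == 0.5, ]
  expect_equal(row$tp, 3); expect_equal(row$fp, 1); expect_equal(row$fn, 1)
  expect_equal(row$fdr, 0.25); expect_equal(row$power, 0.75)
  # CS membership: in-CS SNPs {2,5,6,3}; TP = 2 (2,5), FP = 2 (6,3)
  expect_equal(ev$cs$tp, 2); expect_equal(ev$cs$fp, 2)
  expect_equal(ev$cs$coverage, 2 / 3)
  expect_equal(ev$cs$one_snp_cs_proportion, 2 / 3)
  # perfect recovery
  cs_perfect <- lapply(c(2, 5, 7, 9), function(j)
    list(members = j, purity = 1))
  pipp <- rep(0, 10); pipp[c(2, 5, 7, 9)] <- 1
  evp <- evaluate_finemap(list(pip = pipp, cs = cs_perfect), list(B_true = B))
  expect_equal(evp$cs$fdr, 0)
  expect_equal(evp$cs$power, 1)
  expect_equal(evp$cs$coverage, 1)
  # no CSs at all: coverage is missing, not zero
  ev0 <- evaluate_finemap(list(pip = rep(0, 10), cs = list()),
                          list(B_true = B))
  expect_true(is.na(ev0$cs$coverage))
  expect_equal(ev0$cs$power, 0)
})

test_that("end-to-end simulate/fit/evaluate recovers strong shared signals", {
  sc <- sim_scenario(n = 800, J = 150, R = 3, n_causal = 2, pve = 0.1,
                     sharing_spec = c(equal_all = 0.5, equicorr_all = 0.5),
                     seed = 123)
  dat <- simulate_dataset(sc)
  fit <- mvfine(dat$X, dat$Y, prior = scenario_prior(sc), V = dat$V_true,
                opts = fit_options(L = 5, prior_scale_method = "EM"))
  ev <- evaluate_finemap(fit, dat)
  expect_gte(ev$cs$power, 0.5)
  expect_true(is.na(ev$cs$coverage) || ev$cs$coverage >= 0.5)
  expect_lte(ev$traitwise$fdr %||% 0, 0.5)
})

test_that("scenario_complex builds two sharing groups with correlated noise", {
  sc <- scenario_complex(R = 6, seed = 2)
  expect_length(sc$components, 3)
  expect_equal(sc$trait_corr[1, 2], 0.3)
  expect_equal(sc$trait_corr[1, 6], 0)
  p <- scenario_prior(sc)
  expect_equal(p$K, 3)
  dat <- simulate_dataset(sc)
  expect_equal(dim(dat$Y), c(800, 6))
})
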