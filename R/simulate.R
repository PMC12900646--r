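# Synthetic-data generator: block-LD genotypes, sparse multitrait causal
# effects drawn from named sharing patterns, correlated residuals with a
# per-trait variance-explained target, plus the power/FDR/coverage
# evaluation metrics used to benchmark fine-mapping output.

#' Define a simulation scenario
#'
#' A complete stated world for one simulated fine-mapping region. The
#' defaults emulate the "trait-specific + shared effects" setting: a
#' region of block-autoregressive LD genotypes, 1-2 causal SNPs whose
#' effect rows are either specific to one trait, equal across all traits,
#' or equicorrelated across all traits, independent trait residuals, and a
#' per-trait proportion of variance explained of 0.05 (which at the default
#' n puts per-causal-SNP |z| in roughly the 6-15 range typical of
#' fine-mapping regions).
#'
#' @param n Sample size (default 800).
#' @param J Number of SNPs (default 400).
#' @param R Number of traits (default 5).
#' @param n_causal Number of causal SNPs, 1-5 (default 2).
#' @param sharing_spec Named numeric vector of pattern probabilities over
#'   `"trait_specific"`, `"equal_pair"`, `"equal_half"`, `"equicorr_all"`,
#'   `"equal_all"`; must sum to 1. Default
#'   `c(trait_specific = 0.4, equal_all = 0.3, equicorr_all = 0.3)`.
#' @param equicorr_rho Correlation of the equicorrelated pattern (default
#'   0.5).
#' @param pve Per-trait proportion of variance explained by the causal SNPs
#'   (default 0.05), for traits carrying any signal.
#' @param trait_corr R x R residual correlation matrix, or a scalar
#'   exchangeable correlation (default 0 = independent traits).
#' @param maf_range Minor allele frequency range (default c(0.05, 0.5)).
#' @param ld_block_size SNPs per independent LD block (default 20).
#' @param ld_rho Latent AR(1) correlation within a block (default 0.9).
#' @param components Optional list of R x R covariance components to draw
#'   causal rows from instead of the named patterns (the "complex shared
#'   effects" route).
#' @param seed Integer seed; the same scenario yields byte-identical data.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(n = 800, J = 400, R = 5, n_causal = 2,
                         sharing_spec = c(trait_specific = 0.4,
                                          equal_all = 0.3,
                                          equicorr_all = 0.3),
                         equicorr_rho = 0.5, pve = 0.05, trait_corr = 0,
                         maf_range = c(0.05, 0.5), ld_block_size = 20,
                         ld_rho = 0.9, components = NULL, seed = 1L) {
  stopifnot(n >= 2, J >= 1, R >= 1, n_causal >= 1, n_causal <= min(5, J),
            pve > 0, pve < 1, abs(ld_rho) < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  if (is.null(components)) {
    stopifnot(abs(sum(sharing_spec) - 1) < 1e-8, all(sharing_spec >= 0))
    known <- c("trait_specific", "equal_pair", "equal_half",
               "equicorr_all", "equal_all")
    if (!all(names(sharing_spec) %in% known))
      stop("unknown sharing pattern(s): ",
           paste(setdiff(names(sharing_spec), known), collapse = ", "))
  }
  if (length(trait_corr) == 1) {
    tc <- matrix(trait_corr, R, R)
    diag(tc) <- 1
    trait_corr <- tc
  }
  stopifnot(nrow(trait_corr) == R, min_eigval(trait_corr) > -1e-10)
  structure(list(n = n, J = J, R = R, n_causal = n_causal,
                 sharing_spec = sharing_spec, equicorr_rho = equicorr_rho,
                 pve = pve, trait_corr = trait_corr,
                 maf_range = maf_range, ld_block_size = ld_block_size,
                 ld_rho = ld_rho, components = components,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Two-group "complex shared effects" scenario
#'
#' A stand-in for sharing structure estimated from real blood cell traits:
#' traits split into two groups (e.g. red-cell-like and white-cell-like)
#' with strong within-group effect sharing and correlated residuals.
#'
#' @param R Number of traits (split as evenly as possible into two groups).
#' @param within_share Within-group effect correlation (default 0.8).
#' @param resid_within Within-group residual correlation (default 0.3).
#' @param ... Passed to [sim_scenario()].
#' @return A `sim_scenario` with `components` set to the group patterns.
#' @export
scenario_complex <- function(R = 6, within_share = 0.8,
                             resid_within = 0.3, ...) {
  g1 <- seq_len(ceiling(R / 2))
  g2 <- setdiff(seq_len(R), g1)
  block <- function(idx) {
    U <- matrix(0, R, R)
    U[idx, idx] <- within_share
    diag(U)[idx] <- 1
    U
  }
  comps <- list(group1 = block(g1), group2 = block(g2),
                broad = {
                  U <- matrix(0.25, R, R)
                  diag(U) <- 1
                  U
                })
  Vc <- matrix(0, R, R)
  Vc[g1, g1] <- resid_within
  Vc[g2, g2] <- resid_within
  diag(Vc) <- 1
  sim_scenario(R = R, components = comps, trait_corr = Vc, ...)
}

#' Mixture prior matching a scenario's generating distribution
#'
#' Builds the exact component list and weights the simulator draws causal
#' effect rows from, so calibration experiments can supply the generating
#' prior to the fitter. Only defined for scenarios whose sharing patterns
#' have an enumerable component list (`trait_specific` expands to R
#' singleton components with its probability split evenly; `equal_pair`
#' expands to all SNP pairs similarly).
#'
#' @param scenario A `sim_scenario`.
#' @return A `mix_prior`.
#' @export
scenario_prior <- function(scenario) {
  R <- scenario$R
  if (!is.null(scenario$components))
    return(mix_prior(scenario$components))
  comps <- list(); w <- numeric(0)
  sp <- scenario$sharing_spec
  for (pat in names(sp)) {
    p <- sp[[pat]]
    if (p <= 0) next
    if (pat == "trait_specific") {
      for (r in seq_len(R)) {
        U <- matrix(0, R, R); U[r, r] <- 1
        comps[[paste0("singleton_", r)]] <- U
        w <- c(w, p / R)
      }
    } else if (pat == "equal_all") {
      comps[["equal_all"]] <- matrix(1, R, R)
      w <- c(w, p)
    } else if (pat == "equicorr_all") {
      U <- matrix(scenario$equicorr_rho, R, R); diag(U) <- 1
      comps[["equicorr_all"]] <- U
      w <- c(w, p)
    } else if (pat == "equal_pair") {
      prs <- utils::combn(R, 2)
      for (i in seq_len(ncol(prs))) {
        U <- matrix(0, R, R)
        U[prs[, i], prs[, i]] <- 1
        comps[[paste0("pair_", prs[1, i], "_", prs[2, i])]] <- U
        w <- c(w, p / ncol(prs))
      }
    } else {
      stop("no enumerable component list for pattern '", pat, "'")
    }
  }
  mix_prior(comps, weights = w)
}

#' Simulate block-LD genotype dosages
#'
#' Genotypes are generated from two latent haplotypes per individual. Each
#' haplotype's latent Gaussian follows an AR(1) process with correlation
#' `ld_rho` along SNPs within a block (blocks are independent), and is
#' thresholded at the quantile of each SNP's drawn minor allele frequency,
#' so dosages are 0/1/2, in Hardy-Weinberg equilibrium, with LD decaying
#' geometrically within blocks.
#'
#' @param n,J Sample and SNP counts.
#' @param maf_range MAF range (subset of (0, 0.5]).
#' @param ld_block_size,ld_rho Block structure.
#' @param seed Integer seed (deterministic output).
#' @return List with `X` (n x J dosage matrix) and `maf` (length J).
#' @export
simulate_genotypes <- function(n, J, maf_range = c(0.05, 0.5),
                               ld_block_size = 20, ld_rho = 0.9,
                               seed = 1L) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  with_seed(seed, {
    maf <- stats::runif(J, maf_range[1], maf_range[2])
    X <- matrix(0L, n, J)
    starts <- seq(1, J, by = ld_block_size)
    for (hap in 1:2) {
      for (s in starts) {
        cols <- s:min(s + ld_block_size - 1, J)
        G <- matrix(0, n, length(cols))
        G[, 1] <- stats::rnorm(n)
        if (length(cols) > 1)
          for (jj in 2:length(cols))
            G[, jj] <- ld_rho * G[, jj - 1] +
              sqrt(1 - ld_rho^2) * stats::rnorm(n)
        thr <- stats::qnorm(maf[cols])
        X[, cols] <- X[, cols] +
          (G < matrix(thr, n, length(cols), byrow = TRUE))
      }
    }
    list(X = X, maf = maf)
  })
}

# Draw one causal effect row for a given pattern.
draw_effect_row <- function(pattern, R, equicorr_rho) {
  b <- numeric(R)
  if (pattern == "trait_specific") {
    b[sample.int(R, 1)] <- stats::rnorm(1)
  } else if (pattern == "equal_all") {
    b[] <- stats::rnorm(1)
  } else if (pattern == "equal_pair") {
    if (R < 2) stop("equal_pair pattern needs R >= 2")
    b[sample.int(R, 2)] <- stats::rnorm(1)
  } else if (pattern == "equal_half") {
    h <- max(1, floor(R / 2))
    b[sample.int(R, h)] <- stats::rnorm(1)
  } else if (pattern == "equicorr_all") {
    U <- matrix(equicorr_rho, R, R); diag(U) <- 1
    b <- drop(t(chol(U)) %*% stats::rnorm(R))
  } else stop("unknown pattern: ", pattern)
  b
}

# Draw from N(0, U) for possibly singular U.
draw_mvn_singular <- function(U) {
  e <- eigen(symmetrize(U), symmetric = TRUE)
  pos <- e$values > 1e-12 * max(e$values[1], 1)
  v <- e$vectors[, pos, drop = FALSE]
  drop(v %*% (sqrt(e$values[pos]) * stats::rnorm(sum(pos))))
}

#' Simulate the true effect matrix for a scenario
#'
#' Draws `n_causal` causal SNPs uniformly without replacement and fills
#' each causal row from its assigned sharing pattern (or from a supplied
#' covariance component, for complex-sharing scenarios). All other rows
#' are zero.
#'
#' @param scenario A `sim_scenario`.
#' @param seed Optional seed override.
#' @return List with `B` (J x R), `causal` (indices), `patterns`
#'   (character, per causal SNP).
#' @export
simulate_effects <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  J <- scenario$J; R <- scenario$R
  if (scenario$n_causal > J) stop("n_causal exceeds the number of SNPs")
  with_seed(seed %||% (scenario$seed + 1L), {
    causal <- sort(sample.int(J, scenario$n_causal))
    B <- matrix(0, J, R)
    pats <- character(scenario$n_causal)
    for (i in seq_along(causal)) {
      if (!is.null(scenario$components)) {
        k <- sample.int(length(scenario$components), 1)
        pats[i] <- names(scenario$components)[k] %||% paste0("comp", k)
        b <- draw_mvn_singular(scenario$components[[k]])
      } else {
        pats[i] <- sample(names(scenario$sharing_spec), 1,
                          prob = scenario$sharing_spec)
        b <- draw_effect_row(pats[i], R, scenario$equicorr_rho)
      }
      # guard against an exactly zero draw (causal rows must be nonzero)
      while (all(b == 0)) b <- draw_effect_row("equal_all", R, 0)
      B[causal[i], ] <- b
    }
    list(B = B, causal = causal, patterns = pats)
  })
}

#' Simulate traits given genotypes and effects
#'
#' Rescales each trait's effect column so the realized genetic variance
#' over total variance (realized genetic variance plus the residual
#' variance implied by `trait_corr`) equals `pve` exactly for traits with
#' any signal, then adds residual rows drawn from N(0, V_true) and centers
#' the trait columns. Rescaling makes the output invariant to the overall
#' magnitude of the input effects.
#'
#' @param X n x J genotype matrix.
#' @param B_true J x R effect matrix (will be rescaled).
#' @param trait_corr R x R residual correlation matrix.
#' @param pve Target per-trait proportion of variance explained.
#' @param seed Integer seed.
#' @return List with `Y`, `B` (rescaled effects), `V_true`.
#' @export
simulate_traits <- function(X, B_true, trait_corr, pve, seed = 1L) {
  n <- nrow(X); R <- ncol(B_true)
  V_true <- symmetrize(as.matrix(trait_corr))
  G <- X %*% B_true
  vg <- apply(G, 2, stats::var)
  if (pve > 0 && all(vg == 0))
    stop("pve > 0 requested but no trait has genetic variance")
  s <- ifelse(vg > 0, sqrt(pve * diag(V_true) / ((1 - pve) * vg)), 0)
  B <- sweep(B_true, 2, s, "*")
  with_seed(seed, {
    E <- matrix(stats::rnorm(n * R), n, R) %*% chol(V_true)
    Y <- X %*% B + E
    Y <- scale(Y, center = TRUE, scale = FALSE)
    attributes(Y) <- attributes(Y)["dim"]
    list(Y = Y, B = B, V_true = V_true)
  })
}

#' Simulate a complete fine-mapping dataset
#'
#' Composes [simulate_genotypes()], [simulate_effects()] and
#' [simulate_traits()] for a scenario. Deterministic given the scenario
#' (including its seed).
#'
#' @param scenario A `sim_scenario`.
#' @return List of class `sim_dataset`: `X`, `Y`, `B_true` (on the trait
#'   scale actually used), `causal`, `patterns`, `V_true`, `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  g <- simulate_genotypes(scenario$n, scenario$J, scenario$maf_range,
                          scenario$ld_block_size, scenario$ld_rho,
                          seed = scenario$seed)
  ef <- simulate_effects(scenario)
  tr <- simulate_traits(g$X, ef$B, scenario$trait_corr, scenario$pve,
                        seed = scenario$seed + 2L)
  structure(list(X = g$X, Y = tr$Y, B_true = tr$B, causal = ef$causal,
                 patterns = ef$patterns, maf = g$maf, V_true = tr$V_true,
                 scenario = scenario),
            class = "sim_dataset")
}

#' Evaluate fine-mapping output against simulation truth
#'
#' Computes the standard benchmarking metrics. Cross-trait SNP-wise calls
#' use a sweep of PIP thresholds, giving a power-FDR curve with
#' FDR = FP/(TP+FP) and power = TP/(TP+FN); a cross-trait causal SNP is one
#' with a nonzero true effect on at least one trait. CS-based metrics:
#' coverage (proportion of credible sets containing a true causal SNP;
#' `NA` when there are no sets), power (proportion of causal SNPs inside at
#' least one set), the proportion of 1-SNP sets, median purity and the set
#' size histogram. Trait-wise calls compare `lfsr_snp < lfsr_threshold`
#' against the per-trait truth `b_jr != 0`.
#'
#' @param fit An `mvfine_fit` with summaries attached (or a list with
#'   elements `pip`, `cs`, `lfsr_snp`).
#' @param truth A `sim_dataset` (or list with `B_true`).
#' @param lfsr_threshold Trait-wise significance threshold (default 0.05).
#' @param pip_grid Thresholds for the power-FDR sweep.
#' @return List of class `eval_report`; see Details.
#' @export
evaluate_finemap <- function(fit, truth, lfsr_threshold = 0.05,
                             pip_grid = seq(0, 0.99, by = 0.01)) {
  B <- truth$B_true %||% truth$B
  causal <- which(rowSums(B != 0) > 0)
  J <- nrow(B)
  pip <- fit$pip
  curve <- do.call(rbind, lapply(pip_grid, function(t) {
    call <- which(pip > t)
    tp <- length(intersect(call, causal))
    fp <- length(setdiff(call, causal))
    fn <- length(setdiff(causal, call))
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
               fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
               power = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }))
  cs <- fit$cs %||% list()
  in_cs <- unique(unlist(lapply(cs, `[[`, "members")))
  tp_cs <- length(intersect(in_cs, causal))
  fp_cs <- length(setdiff(in_cs, causal))
  fn_cs <- length(setdiff(causal, in_cs))
  cs_cover <- if (length(cs) == 0) NA_real_ else
    mean(vapply(cs, function(x) any(x$members %in% causal), TRUE))
  sizes <- vapply(cs, function(x) length(x$members), 0L)
  # trait-wise calls from SNP-wise lfsr
  tw <- NULL
  if (!is.null(fit$lfsr_snp)) {
    call_tw <- fit$lfsr_snp < lfsr_threshold
    true_tw <- B != 0
    tp <- sum(call_tw & true_tw); fp <- sum(call_tw & !true_tw)
    fn <- sum(!call_tw & true_tw)
    tw <- list(tp = tp, fp = fp, fn = fn,
               fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
               power = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  structure(list(
    pip_curve = curve,
    cs = list(tp = tp_cs, fp = fp_cs, fn = fn_cs,
              fdr = if (tp_cs + fp_cs > 0) fp_cs / (tp_cs + fp_cs)
                    else NA_real_,
              power = if (tp_cs + fn_cs > 0) tp_cs / (tp_cs + fn_cs)
                      else NA_real_,
              coverage = cs_cover,
              n_cs = length(cs),
              one_snp_cs_proportion = if (length(cs)) mean(sizes == 1)
                                      else NA_real_,
              median_purity = if (length(cs))
                stats::median(vapply(cs, `[[`, 0, "purity")) else NA_real_,
              cs_size_histogram = table(sizes)),
    traitwise = tw,
    lfsr_threshold = lfsr_threshold),
    class = "eval_report")
}

#' Arithmetic core of the FDR/power metrics
#'
#' @param tp,fp,fn True positive, false positive and false negative counts.
#' @return List with `fdr = fp/(tp+fp)` and `power = tp/(tp+fn)` (`NA`
#'   where the denominator is zero).
#' @export
fdr_power <- function(tp, fp, fn) {
  list(fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
       power = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
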