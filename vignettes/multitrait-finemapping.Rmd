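---
title: "Multitrait fine-mapping with mvfine: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitrait fine-mapping with mvfine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvfine)
```

## The problem

A genetic association region typically contains hundreds to thousands of
SNPs in strong linkage disequilibrium (LD), of which only a handful causally
affect any trait. Fine-mapping asks which. When several related traits are
measured on the same cohort (e.g. blood cell indices), analyzing them
jointly can sharpen the answer: a SNP whose effect is shared across traits
accumulates evidence from all of them, and the pattern of sharing itself is
biologically informative. `mvfine` implements a multivariate sum of single
effects regression for this task, fitting either individual-level data
(genotypes `X`, traits `Y`) or GWAS summary data (z-scores, an LD matrix
and the sample size).

## Model

For $n$ individuals, $J$ SNPs and $R$ traits, the traits follow a matrix
normal multivariate regression
$$Y \sim MN_{n\times R}(XB,\, I_n,\, V),$$
with $B \in \mathbb{R}^{J \times R}$ the effect matrix and $V$ the residual
covariance across traits (residuals are independent across individuals but
may be correlated across traits). There is no explicit intercept: columns
of $X$ and $Y$ are centered, which is equivalent to integrating an
improper flat prior over per-trait intercepts.

The coefficients decompose into $L$ *single effects*,
$$B = \sum_{l=1}^L B^{(l)}, \qquad
  B^{(l)} = \gamma^{(l)} \otimes b^{(l)},$$
where $\gamma^{(l)} \in \{0,1\}^J$ selects exactly one SNP
($\gamma^{(l)} \sim \mathrm{Multinom}(1, \pi)$, uniform $\pi$ by default)
and $b^{(l)} \in \mathbb{R}^R$ is that SNP's vector of effects on the $R$
traits. The prior on $b^{(l)}$ is a mixture of multivariate normals,
$$g_l(b) = \sum_{k=1}^K \omega_k\, N_R(b;\, 0,\, \sigma^2_{0l} U_k),$$
whose covariance components $U_k$ encode effect-sharing patterns:
trait-specific singletons $e_r e_r^\top$, independent effects (identity;
the "random effects" special case), equal effects in all traits (all-ones;
the "fixed effects" special case), equicorrelated patterns, or components
learned from data. Components may be singular; all posterior algebra is
singular-safe (no $U_k^{-1}$ is ever formed). The per-effect scales
$\sigma^2_{0l}$ are nuisance parameters estimated from the data; $V$, the
$U_k$ and $\omega$ are fixed inputs to the fitter, estimated upstream.

## Fitting

The model is fit by Iterative Bayesian Stepwise Selection (IBSS): cycling
over effects $l = 1, \dots, L$, each single effect is refit exactly against
the residual sufficient statistics left by the posterior means of the
others. The inner solve (the single-effect regression) is exact and
conjugate: per SNP $j$, with least-squares row estimate
$\hat b_j = x_j^\top Y / x_j^\top x_j$ and sampling covariance
$S_j = V / x_j^\top x_j$, each component contributes
$$\log BF_{jk} = \log N(\hat b_j; 0, S_j + \sigma^2_{0l} U_k)
              - \log N(\hat b_j; 0, S_j),$$
and inclusion probabilities $\alpha_j \propto \pi_j \exp(\mathrm{lbf}_j)$
are accumulated entirely in log space. Convergence is monitored through a
variational evidence lower bound (ELBO) that is non-decreasing across
iterations and exact at $L \le 1$; iteration stops when it changes by less
than `tol` (default $10^{-3}$).

### Numerical and design choices

* **Prior scale estimation.** Two methods are provided. `"optim"`
  (default) maximizes the single-effect log Bayes factor over
  $\log \sigma^2$ with a Brent search; `"EM"` takes one EM step per update
  using posterior second moments through the generalized inverses of the
  $U_k$ (restricted to each component's column space). Both are ascent
  steps on the effect's marginal likelihood; `"EM"` is considerably
  cheaper per update and is what the large simulation checks use.
* **Null effects.** $\sigma^2 = 0$ is a permitted maximizer: when the best
  Bayes factor found does not exceed the null's, the scale is set to zero
  and the effect's posterior falls back to the uniform prior. Because a
  scale maximized over a continuum retains tiny spurious positive evidence
  on pure noise (of order $10^{-3}$ in log Bayes factor), effects are
  *classified* as active for reporting only if their final single-effect
  log Bayes factor exceeds `check_null_threshold` (default 0.1). The
  classification happens after convergence, so the ELBO trace remains a
  monotone coordinate ascent; zeroing such effects mid-iteration would
  trade a guaranteed ascent property for marginally more aggressive
  pruning.
* **Shared precomputation.** When genotype columns are standardized,
  $x_j^\top x_j$ is constant across SNPs and all $R \times R$ solves and
  log-determinants are computed once per component rather than per SNP.
  The general case groups SNPs by their $x_j^\top x_j$ value.
* **Ties.** SNPs tied in $\alpha$ are ordered by index everywhere, so
  outputs are deterministic.
* **Degenerate input.** A single-SNP region returns a certain single
  effect rather than an error; monomorphic genotype columns are dropped
  with a warning.

## Summary data (RSS)

The summary-level interface rebuilds sufficient statistics from a
$J \times R$ z-score matrix $Z$, an LD matrix $R_{\mathrm{ld}}$ and the
sample size under the standardized-genotype, standardized-trait
convention:
$$X^\top X = (n-1) R_{\mathrm{ld}}, \quad
  X^\top Y = \sqrt{n-1}\, Z, \quad
  Y^\top Y = (n-1) V.$$
With in-sample LD and z-scores computed under the same convention
(`individual_to_rss()`), the summary fit reproduces the individual-level
fit (the package's tests require agreement within $10^{-6}$ in PIP). The
finite-sample standard-error adjustment some single-trait methods apply is
deliberately omitted: $V$ is supplied or estimated externally here, and the
omission is $O(z^2/n)$. The residual trait correlation is estimated from
the *weakest* signals — rows with $\max_r |z_{jr}|$ below a threshold
(default 2) — whose sample correlation estimates $V$ under the null;
near-singular estimates are shrunk toward the identity. Note that
truncating to null rows slightly attenuates the estimated correlations;
with the default threshold the attenuation is modest and the fits are
robust to it, and an explicit `V` can always be supplied.

## Reported summaries

* **Cross-trait PIP**: $\mathrm{PIP}_j = 1 - \prod_{l\,\text{active}}
  (1 - \alpha_{lj})$, the probability SNP $j$ is causal for at least one
  trait.
* **Credible sets**: per active effect, the smallest prefix of SNPs (by
  descending $\alpha$) whose cumulative probability reaches the coverage
  level (default 0.95). Sets with *purity* — the minimum absolute pairwise
  LD among members — below 0.5 are removed; exact-duplicate sets keep the
  higher-evidence effect. Purity of sets larger than 100 SNPs is computed
  on the top 100 members by $\alpha$ (deterministic), and attained
  coverage is reported since the discrete prefix overshoots the nominal
  level. The member with the highest PIP is the set's *sentinel* SNP.
* **Trait-wise significance (lfsr)**: the local false sign rate is the
  posterior probability that an effect is zero or its sign is called
  wrong. Two granularities are reported. The CS-level "average lfsr" per
  trait is the $\alpha$-weighted mixture tail probability
  $1 - \max\big(\sum_j \alpha_j P(b_r > 0 \mid j),\,
  \sum_j \alpha_j P(b_r < 0 \mid j)\big)$; a set is significant for trait
  $r$ when it falls below 0.01. (The unweighted average of SNP-wise lfsr
  over members is also computed, but the $\alpha$-weighted version is the
  default and the one reported.) Posterior point mass at exactly zero
  counts toward neither strict tail, so an effect confined to a
  trait-specific component has lfsr 1 in the other traits.
* **SNP-wise lfsr for calling**: conditional SNP-wise lfsr (given the SNP
  is the causal one) is available from `ser_lfsr()`, but any SNP in LD
  with a signal has a confident *conditional* sign, so per-SNP calling
  uses the inclusion-aware version $1 - \alpha_j \max(P^+_{jr}, P^-_{jr})$
  minimized over active effects. This is what the reports and the
  evaluation metrics consume.
* **max-PIP**: for comparison with per-trait single-trait analyses,
  $\mathrm{maxPIP}_j = \max_r \mathrm{PIP}_{jr}$ combines per-trait PIPs
  into a cross-trait measure.

## The simulator and what it does (and does not) emulate

`simulate_dataset()` generates a complete stated world per region:

* **Genotypes** from two latent AR(1) haplotypes per individual,
  thresholded at each SNP's drawn minor allele frequency
  (range 0.05–0.5), so dosages are 0/1/2 in Hardy–Weinberg equilibrium
  with block LD (default blocks of 20 SNPs, latent correlation 0.9).
  Thresholding attenuates dosage LD relative to the latent correlation;
  blocks are exactly independent, unlike real recombination landscapes.
* **Effects**: 1–5 causal SNPs drawn uniformly; each causal row drawn from
  a named sharing pattern (trait-specific, equal on a pair, equal on half,
  equal on all, equicorrelated across all) or from supplied covariance
  components. The default sharing specification — trait-specific 0.4,
  equal-across-all 0.3, equicorrelated (rho 0.5) 0.3 — was chosen once so
  that the *exact* generating mixture prior is enumerable
  (`scenario_prior()`) and can be handed to the fitter in calibration
  experiments; the pair/half patterns remain available but their exact
  mixture prior is combinatorial in $R$. `scenario_complex()` provides a
  two-group world (strong within-group sharing, correlated residuals)
  standing in for multi-cell-type trait panels.
* **Traits**: effects are rescaled so the realized per-trait genetic
  variance over total variance equals the target `pve` (default 0.05)
  exactly for traits carrying signal, with residual rows drawn from the
  specified trait correlation. At the default $n = 800$ this puts
  per-causal-SNP |z| roughly in the 6–15 range seen in fine-mapping
  regions; targeting pve rather than a z-score distribution is a declared
  substitute for simulations that use real biobank LD.

A green calibration test therefore establishes that the method is
calibrated *under its own model with block-LD genotypes and the generating
prior supplied* — not that it is robust to LD reference mismatch, model
misspecification of the prior, non-normal traits or real recombination
structure. The large-scale checks use `prior_scale_method = "EM"` and
$L = 5$ (the worlds contain at most 2 causal SNPs) to keep runtimes
within a test-suite budget; defaults for interactive use are `"optim"`
and $L = 10$.

## Example

```{r example}
sc <- sim_scenario(n = 600, J = 200, R = 3, n_causal = 2, pve = 0.08,
                   seed = 11)
dat <- simulate_dataset(sc)
fit <- mvfine(dat$X, dat$Y, prior = scenario_prior(sc), V = dat$V_true,
              opts = fit_options(L = 5))
summary(fit)
evaluate_finemap(fit, dat)$cs[c("power", "coverage", "median_purity")]
```

## Known limitations

* $V$ is fixed during fitting; there is no within-IBSS residual
  covariance update, and no "refine" restart heuristic.
* No handling of per-trait missingness, binary traits, or allele
  harmonization against a reference; LD must be precomputed and aligned.
* Reference-panel LD is accepted (and tagged as such) but mismatch
  diagnostics are out of scope for this version.
* The data-driven prior learner is a zero-mean extreme deconvolution EM;
  it does not implement a full grid-based sharing-pattern pipeline with
  per-effect posterior summaries across conditions.
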