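# Posterior summaries: cross-trait PIPs, purity-filtered credible sets,
# per-trait average lfsr significance calls, and the max-PIP combiner used
# to compare with per-trait single-trait fine-mapping.

#' Cross-trait posterior inclusion probabilities
#'
#' PIP_j = 1 - prod over active effects of (1 - alpha_lj): the posterior
#' probability that SNP j is causal for at least one trait. Pruned (null)
#' effects are excluded.
#'
#' @param fit An `mvfine_fit`.
#' @return Length-J vector in [0, 1].
#' @export
compute_pip <- function(fit) {
  J <- fit$J
  act <- fit$active_effects
  if (length(act) == 0) return(rep(0, J))
  one_minus <- rep(1, J)
  for (l in act) one_minus <- one_minus * (1 - fit$sers[[l]]$alpha)
  pmin(pmax(1 - one_minus, 0), 1)
}

# Purity = smallest absolute pairwise genotype correlation among CS
# members; computed on the top `max_snps` members by alpha for very large
# sets (deterministic), as is standard practice.
cs_purity <- function(members, ld, max_snps = 100) {
  if (length(members) == 1) return(1)
  if (length(members) > max_snps) members <- members[seq_len(max_snps)]
  sub <- abs(ld[members, members])
  min(sub[upper.tri(sub)])
}

#' Credible sets from a fitted model
#'
#' For each active single effect, sorts SNPs by inclusion probability
#' (ties broken by lowest index) and takes the smallest prefix whose
#' cumulative probability reaches the coverage level. Sets whose purity
#' (minimum absolute pairwise LD among members) falls below
#' `purity_threshold` are removed; exact-duplicate member sets arising from
#' effects that converged on the same signal are deduplicated keeping the
#' effect with the larger single-effect log Bayes factor.
#'
#' @param fit An `mvfine_fit`.
#' @param ld J x J SNP correlation matrix aligned with the fit (default:
#'   the LD stored in the fit, if any).
#' @param coverage Target coverage level (default 0.95).
#' @param purity_threshold Minimum purity to retain a set (default 0.5).
#' @return List of `credible_set` objects, each with `effect_index`,
#'   `members` (descending alpha), `coverage_level`, `attained_coverage`,
#'   `purity`, `sentinel`, `one_snp` flag and `lbf_model`.
#' @export
compute_cs <- function(fit, ld = NULL, coverage = 0.95,
                       purity_threshold = 0.5) {
  ld <- ld %||% fit$ld
  if (is.null(ld)) stop("an LD matrix is required to compute credible sets")
  if (nrow(ld) != fit$J) stop("LD matrix does not match the fit (J mismatch)")
  pip <- compute_pip(fit)
  out <- list()
  for (l in fit$active_effects) {
    a <- fit$sers[[l]]$alpha
    ord <- order(-a, seq_along(a))
    cum <- cumsum(a[ord])
    m <- which(cum >= coverage)[1]
    if (is.na(m)) m <- length(a)
    members <- ord[seq_len(m)]
    pur <- cs_purity(members, ld)
    if (pur < purity_threshold) next
    sentinel <- members[which.max(pip[members])]
    out[[length(out) + 1]] <- structure(
      list(effect_index = l, members = members,
           snp_ids = fit$snp_ids[members],
           coverage_level = coverage, attained_coverage = cum[m],
           purity = pur, sentinel = sentinel,
           sentinel_id = fit$snp_ids[sentinel],
           one_snp = length(members) == 1,
           lbf_model = fit$sers[[l]]$lbf_model),
      class = "credible_set")
  }
  # deduplicate identical member sets, keeping the higher-evidence effect
  if (length(out) > 1) {
    keys <- vapply(out, function(cs) paste(sort(cs$members), collapse = ","),
                   "")
    keep <- rep(TRUE, length(out))
    for (key in unique(keys)) {
      idx <- which(keys == key)
      if (length(idx) > 1) {
        best <- idx[which.max(vapply(out[idx], `[[`, 0, "lbf_model"))]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    out <- out[keep]
  }
  out
}

#' Annotate credible sets with per-trait significance
#'
#' Attaches to each credible set the effect-level ("average") lfsr per
#' trait, and the set of traits for which it falls below the significance
#' threshold. A set may be significant in zero traits.
#'
#' @param cs_list Output of [compute_cs()].
#' @param fit The `mvfine_fit` the sets came from.
#' @param lfsr_threshold Per-trait significance threshold (default 0.01).
#' @return `cs_list` with `avg_lfsr` (length-R vector) and
#'   `significant_traits` (integer indices) added to each set.
#' @export
cs_significance <- function(cs_list, fit, lfsr_threshold = 0.01) {
  lapply(cs_list, function(cs) {
    lf <- ser_lfsr(fit$sers[[cs$effect_index]])
    cs$avg_lfsr <- lf$effect
    cs$significant_traits <- which(lf$effect < lfsr_threshold)
    cs$lfsr_threshold <- lfsr_threshold
    cs
  })
}

#' Combine per-trait PIPs by their maximum
#'
#' The cross-trait evidence measure for a SNP from separate single-trait
#' analyses: max-PIP_j = max over traits r of PIP_jr.
#'
#' @param per_trait_pips J x R matrix of per-trait PIPs in [0, 1].
#' @return Length-J vector.
#' @export
max_pip <- function(per_trait_pips) {
  P <- as.matrix(per_trait_pips)
  stopifnot(all(P >= 0 & P <= 1))
  apply(P, 1, max)
}

# SNP-wise lfsr matrix for calling: minimum over active effects of the
# per-effect inclusion-aware lfsr (1 when no effect is active).
snp_lfsr <- function(fit) {
  out <- matrix(1, fit$J, fit$R)
  for (l in fit$active_effects)
    out <- pmin(out, ser_lfsr(fit$sers[[l]])$snp_weighted)
  out
}

# Attach pip/cs/lfsr summaries to a fit (used by mvfine / mvfine_rss).
attach_summaries <- function(fit, coverage = 0.95, purity_threshold = 0.5,
                             lfsr_threshold = 0.01) {
  fit$pip <- compute_pip(fit)
  fit$cs <- cs_significance(
    compute_cs(fit, coverage = coverage,
               purity_threshold = purity_threshold),
    fit, lfsr_threshold = lfsr_threshold)
  fit$lfsr_snp <- snp_lfsr(fit)
  fit$coverage <- coverage
  fit$purity_threshold <- purity_threshold
  fit$lfsr_threshold <- lfsr_threshold
  fit
}

#' @export
summary.mvfine_fit <- function(object, ...) {
  cs <- object$cs %||% list()
  df <- if (length(cs)) data.frame(
    cs = seq_along(cs),
    effect = vapply(cs, `[[`, 0L, "effect_index"),
    size = vapply(cs, function(x) length(x$members), 0L),
    sentinel = vapply(cs, `[[`, "", "sentinel_id"),
    coverage = vapply(cs, `[[`, 0, "attained_coverage"),
    purity = vapply(cs, `[[`, 0, "purity"),
    n_sig_traits = vapply(cs, function(x)
      length(x$significant_traits %||% integer(0)), 0L)
  ) else data.frame()
  out <- list(n_cs = length(cs), cs_table = df,
              n_active = length(object$active_effects),
              top_pip = utils::head(sort(object$pip, decreasing = TRUE), 5))
  class(out) <- "summary.mvfine_fit"
  out
}

#' @export
print.summary.mvfine_fit <- function(x, ...) {
  cat("Credible sets:", x$n_cs, "( active effects:", x$n_active, ")\n")
  if (nrow(x$cs_table)) print(x$cs_table, row.names = FALSE)
  cat("Top PIPs:", paste(signif(x$top_pip, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Write or read per-SNP and per-CS fine-mapping reports
#'
#' Tab-delimited report writers with full-precision numeric fields, and
#' matching readers that round-trip all numeric fields losslessly.
#' The per-SNP table has columns snp, chr, pos, pip, then one lfsr column
#' per trait; the per-CS table has one row per credible set.
#'
#' @param fit An `mvfine_fit` with summaries attached.
#' @param path Output file path.
#' @param chr,pos Optional coordinate metadata (1-based positions).
#' @param trait_ids Optional trait labels.
#' @return The path, invisibly (writers); a data frame (readers).
#' @export
write_snp_report <- function(fit, path, chr = NA, pos = NA,
                             trait_ids = NULL) {
  trait_ids <- trait_ids %||% paste0("trait", seq_len(fit$R))
  lfsr <- fit$lfsr_snp %||% snp_lfsr(fit)
  colnames(lfsr) <- paste0("lfsr_", trait_ids)
  df <- data.frame(snp = fit$snp_ids, chr = chr, pos = pos,
                   pip = fit$pip, lfsr, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_report
#' @export
read_snp_report <- function(path)
  utils::read.delim(path, check.names = FALSE)

#' @rdname write_snp_report
#' @export
write_cs_report <- function(fit, path, trait_ids = NULL) {
  trait_ids <- trait_ids %||% paste0("trait", seq_len(fit$R))
  cs <- fit$cs %||% list()
  rows <- lapply(seq_along(cs), function(i) {
    x <- cs[[i]]
    lf <- x$avg_lfsr %||% rep(NA_real_, fit$R)
    row <- data.frame(cs = i, effect = x$effect_index,
                      members = paste(x$snp_ids, collapse = ","),
                      size = length(x$members),
                      sentinel = x$sentinel_id,
                      attained_coverage = x$attained_coverage,
                      purity = x$purity, one_snp = x$one_snp,
                      lbf_model = x$lbf_model,
                      significant_traits = paste(
                        trait_ids[x$significant_traits %||% integer(0)],
                        collapse = ","))
    for (r in seq_len(fit$R)) row[[paste0("avg_lfsr_", trait_ids[r])]] <- lf[r]
    row
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cs = integer(0))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_report
#' @export
read_cs_report <- function(path)
  utils::read.delim(path, check.names = FALSE)
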