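# Summary-data (RSS) path: fine-mapping from a J x R z-score matrix, a
# J x J LD matrix and the GWAS sample size n, plus estimation of the
# residual trait correlation matrix V from the weakest (null) signals.
#
# Convention: z_jr is the marginal association z-score of SNP j on trait r
# under column-standardized genotypes and traits, so that
#   XtX = (n-1) R_ld,  XtY = sqrt(n-1) Z,  YtY = (n-1) V.
# With z and LD computed in-sample under the same convention (see
# individual_to_rss), the summary-level fit reproduces the
# individual-level fit.

#' Z-score panel container
#'
#' @param Z J x R matrix of association z-scores (finite entries).
#' @param n GWAS sample size (> 1).
#' @param snp_ids,trait_ids Optional labels.
#' @return Object of class `z_panel`.
#' @export
z_panel <- function(Z, n, snp_ids = NULL, trait_ids = NULL) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("z-score matrix contains non-finite entries")
  stopifnot(n > 1)
  structure(list(Z = Z, n = as.integer(n),
                 snp_ids = snp_ids %||% rownames(Z) %||%
                   paste0("snp", seq_len(nrow(Z))),
                 trait_ids = trait_ids %||% colnames(Z) %||%
                   paste0("trait", seq_len(ncol(Z)))),
            class = "z_panel")
}

#' LD matrix container
#'
#' Validates and wraps a dense SNP correlation matrix. Slightly non-PSD
#' inputs (as arise from reference panels or numerical noise) are
#' eigenvalue-clipped and re-symmetrized, with a message recording the
#' correction.
#'
#' @param R_ld J x J correlation matrix: symmetric, unit diagonal, entries
#'   in [-1, 1].
#' @param source `"in-sample"` or `"reference"`; recorded for provenance.
#' @param snp_ids Optional labels.
#' @return Object of class `ld_matrix`.
#' @export
ld_matrix <- function(R_ld, source = c("in-sample", "reference"),
                      snp_ids = NULL) {
  source <- match.arg(source)
  R_ld <- as.matrix(R_ld)
  if (!is_symmetric_tol(R_ld, 1e-8)) stop("LD matrix must be symmetric")
  if (max(abs(diag(R_ld) - 1)) > 1e-8)
    stop("LD matrix must have unit diagonal")
  if (max(abs(R_ld)) > 1 + 1e-8)
    stop("LD entries must lie in [-1, 1]")
  R_ld <- symmetrize(R_ld)
  ev_min <- min_eigval(R_ld)
  if (ev_min < -1e-6)
    stop("LD matrix is not positive semidefinite (min eigenvalue ",
         signif(ev_min, 3), ")")
  if (ev_min < 0) {
    message("LD matrix slightly non-PSD (min eigenvalue ",
            signif(ev_min, 3), "); clipping negative eigenvalues")
    R_ld <- psd_project(R_ld)
    d <- sqrt(diag(R_ld))
    R_ld <- R_ld / tcrossprod(d)
  }
  structure(list(R_ld = R_ld, source = source,
                 snp_ids = snp_ids %||% rownames(R_ld) %||%
                   paste0("snp", seq_len(nrow(R_ld)))),
            class = "ld_matrix")
}

#' Estimate the residual trait correlation from null z-scores
#'
#' Under the null, marginal z-scores across traits are correlated exactly
#' as the trait residuals are, so the sample correlation of z-score rows at
#' SNPs with no signal in any trait estimates V. Rows with
#' \eqn{\max_r |z_{jr}|} below `null_threshold` are used; at least 50 such
#' rows are required. If the estimate is near-singular it is shrunk toward
#' the identity, \eqn{(1-\lambda)\hat V + \lambda I}, with the smallest
#' \eqn{\lambda} from `0, 0.01, 0.05, 0.1, ...` that brings the condition
#' number below 1e8.
#'
#' @param Z A `z_panel` or a J x R z-score matrix.
#' @param null_threshold Cross-trait |z| below which a SNP counts as null
#'   (default 2).
#' @param min_null Minimum number of null rows required (default 50).
#' @return R x R correlation matrix (unit diagonal, positive definite).
#' @export
estimate_residual_covariance <- function(Z, null_threshold = 2,
                                         min_null = 50) {
  Zm <- if (inherits(Z, "z_panel")) Z$Z else as.matrix(Z)
  null_rows <- apply(abs(Zm), 1, max) < null_threshold
  M <- sum(null_rows)
  if (M < min_null)
    stop("only ", M, " SNPs with max |z| < ", null_threshold,
         "; provide a larger panel or an explicit V")
  Vhat <- stats::cor(Zm[null_rows, , drop = FALSE])
  if (min_eigval(Vhat) < 0) {
    Vhat <- psd_project(Vhat)
    d <- sqrt(pmax(diag(Vhat), .Machine$double.eps))
    Vhat <- Vhat / tcrossprod(d)
  }
  R <- ncol(Vhat)
  for (lam in c(0, 0.01, 0.05, seq(0.1, 1, by = 0.05))) {
    Vs <- (1 - lam) * Vhat + lam * diag(R)
    ev <- eigen(Vs, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < 1e8) return(symmetrize(Vs))
  }
  diag(R)
}

#' Build sufficient statistics from z-scores, LD and sample size
#'
#' Reconstructs the sufficient statistics under the standardized-X,
#' standardized-Y convention: `XtX = (n-1) R_ld`, `XtY = sqrt(n-1) Z`,
#' `YtY = (n-1) V`. With in-sample LD and z-scores computed under the same
#' convention, fitting these statistics reproduces the individual-level
#' fit.
#'
#' @param Z A `z_panel`.
#' @param ld An `ld_matrix` with SNP ids aligned to the panel.
#' @param V R x R residual correlation matrix used for the `YtY`
#'   convention (default: estimated from the panel's null rows).
#' @return A `suff_stats` object; the LD source tag is carried along as
#'   attribute `ld_source`.
#' @export
rss_to_suffstats <- function(Z, ld, V = NULL) {
  stopifnot(inherits(Z, "z_panel"), inherits(ld, "ld_matrix"))
  if (nrow(Z$Z) != nrow(ld$R_ld) ||
      !all(Z$snp_ids == ld$snp_ids)) {
    bad <- union(setdiff(Z$snp_ids, ld$snp_ids),
                 setdiff(ld$snp_ids, Z$snp_ids))
    stop("z panel and LD matrix are misaligned",
         if (length(bad)) paste0("; offending SNPs: ",
                                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  n <- Z$n
  if (is.null(V)) V <- estimate_residual_covariance(Z)
  if (max(abs(Z$Z)) > 0 && max(abs(Z$Z))^2 > 100 * n)
    warning("z-scores look implausibly large for the stated sample size n = ",
            n)
  out <- suff_stats(XtX = (n - 1) * ld$R_ld,
                    XtY = sqrt(n - 1) * Z$Z,
                    YtY = (n - 1) * V,
                    n = n, snp_ids = Z$snp_ids,
                    column_scales = rep(1, nrow(Z$Z)))
  attr(out, "ld_source") <- ld$source
  out
}

#' Multitrait fine-mapping from summary data
#'
#' The summary-data (RSS) interface: fits the sum of single effects model
#' from a z-score matrix, an LD matrix and the sample size, then attaches
#' the standard summaries. The residual trait correlation V is estimated
#' from the panel's null rows unless supplied.
#'
#' @param Z A `z_panel` or J x R z-score matrix.
#' @param ld An `ld_matrix` or J x J correlation matrix.
#' @param n Sample size (required when `Z` is a bare matrix).
#' @param prior A `mix_prior`; default canonical components.
#' @param V Optional residual correlation matrix.
#' @param pi Prior inclusion probabilities (default uniform).
#' @param opts A `fit_options` list.
#' @param coverage,purity_threshold,lfsr_threshold Summary thresholds.
#' @return An `mvfine_fit` with summaries attached; `fit$ld_source` records
#'   whether in-sample or reference LD was used.
#' @export
mvfine_rss <- function(Z, ld, n = NULL, prior = NULL, V = NULL, pi = NULL,
                       opts = fit_options(), coverage = 0.95,
                       purity_threshold = 0.5, lfsr_threshold = 0.01) {
  if (!inherits(Z, "z_panel")) {
    if (is.null(n)) stop("n is required when Z is a bare matrix")
    Z <- z_panel(Z, n)
  }
  if (!inherits(ld, "ld_matrix"))
    ld <- ld_matrix(ld, source = "in-sample", snp_ids = Z$snp_ids)
  if (is.null(V)) V <- estimate_residual_covariance(Z)
  if (is.null(prior)) prior <- mix_prior(canonical_components(ncol(Z$Z)))
  stats <- rss_to_suffstats(Z, ld, V = V)
  fit <- ibss(stats, prior, pi = pi, V = V, opts = opts)
  fit$ld <- ld$R_ld
  fit$ld_source <- ld$source
  attach_summaries(fit, coverage = coverage,
                   purity_threshold = purity_threshold,
                   lfsr_threshold = lfsr_threshold)
}

#' In-sample summary statistics from individual-level data
#'
#' Computes the z-score panel and LD matrix for individual-level data under
#' the package's summary-data convention: after centering and
#' standardization, \eqn{z_{jr} = \sqrt{n-1}\,\mathrm{cor}(x_j, y_r)} and
#' LD is the genotype correlation matrix. Fitting these summaries with
#' [mvfine_rss()] reproduces the [mvfine()] fit on the same data.
#'
#' @param X n x J genotype matrix.
#' @param Y n x R trait matrix.
#' @return List with `Z` (a `z_panel`) and `ld` (an `ld_matrix`).
#' @export
individual_to_rss <- function(X, Y) {
  cs_data <- center_and_standardize(X, Y)
  n <- nrow(cs_data$X)
  Ys <- scale(cs_data$Y, center = FALSE,
              scale = apply(cs_data$Y, 2, stats::sd))
  Zm <- crossprod(cs_data$X, Ys) / sqrt(n - 1)
  list(Z = z_panel(Zm, n), ld = ld_matrix(stats::cor(cs_data$X)))
}

#' Read and write z-score panels and LD matrices
#'
#' The z panel is tab-delimited with header columns `snp`, `chr`, `pos`
#' (1-based; metadata only) followed by one z column per trait. The LD
#' matrix is a dense whitespace-delimited square matrix whose row order
#' matches the panel.
#'
#' @param path File path.
#' @param n Sample size to attach to the panel.
#' @param source LD provenance tag.
#' @return `read_z_panel`: a `z_panel` (with `chr`/`pos` attributes);
#'   `read_ld_matrix`: an `ld_matrix`.
#' @export
read_z_panel <- function(path, n) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("snp", "chr", "pos")
  if (!all(need %in% names(df)))
    stop("z panel must have columns snp, chr, pos, then one z column per trait")
  zc <- setdiff(names(df), need)
  Z <- as.matrix(df[zc])
  rownames(Z) <- df$snp
  out <- z_panel(Z, n, snp_ids = df$snp, trait_ids = zc)
  out$chr <- df$chr
  out$pos <- df$pos
  out
}

#' @rdname read_z_panel
#' @param panel A `z_panel` to write.
#' @export
write_z_panel <- function(panel, path) {
  df <- data.frame(snp = panel$snp_ids,
                   chr = panel$chr %||% NA,
                   pos = panel$pos %||% NA)
  Z <- panel$Z
  colnames(Z) <- panel$trait_ids
  df <- cbind(df, Z)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_z_panel
#' @export
read_ld_matrix <- function(path, source = "in-sample") {
  M <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(M) <- NULL
  ld_matrix(M, source = source)
}

#' @rdname read_z_panel
#' @param ld An `ld_matrix` to write.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(format(ld$R_ld, digits = 17, trim = TRUE,
                            scientific = NA),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
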