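# Sufficient statistics: the common currency of the individual-level and
# summary-level fitting paths. Everything the iterative fitter needs is
# X'X, X'Y, Y'Y and n, computed on centered (and, for X, standardized)
# columns; centering the columns plays the role of an intercept.

#' Center and standardize genotype and trait matrices
#'
#' Centers every column of `X` and `Y` to mean zero (the model handles the
#' intercept implicitly through centering) and scales the genotype columns
#' to unit variance. Monomorphic (zero-variance) genotype columns cannot be
#' fine-mapped and are dropped with a warning. The column scales are
#' recorded so fitted effects can be reported on the original dosage scale
#' (original-scale effect = standardized-scale effect / scale).
#'
#' @param X n x J genotype dosage matrix.
#' @param Y n x R trait matrix.
#' @return List with `X`, `Y`, `column_scales` (length J'), `kept`
#'   (indices of retained SNP columns).
#' @export
center_and_standardize <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  stopifnot(nrow(Y) == n)
  sds <- apply(X, 2, stats::sd)
  kept <- which(sds > 0)
  if (length(kept) < ncol(X))
    warning("dropped ", ncol(X) - length(kept),
            " monomorphic (zero-variance) genotype column(s)")
  X <- X[, kept, drop = FALSE]
  X <- scale(X, center = TRUE, scale = sds[kept])
  Y <- scale(Y, center = TRUE, scale = FALSE)
  list(X = `attributes<-`(X, list(dim = dim(X), dimnames = dimnames(X))),
       Y = `attributes<-`(Y, list(dim = dim(Y), dimnames = dimnames(Y))),
       column_scales = sds[kept], kept = kept)
}

#' Compute sufficient statistics from centered data
#'
#' @param X n x J centered (and usually standardized) genotype matrix.
#' @param Y n x R centered trait matrix.
#' @param snp_ids Optional SNP labels (default: column names of `X`).
#' @param column_scales Optional record of the standardization applied.
#' @return Object of class `suff_stats` with `XtX` (J x J), `XtY` (J x R),
#'   `YtY` (R x R), `n`, `snp_ids`, `column_scales`.
#' @export
compute_sufficient_stats <- function(X, Y, snp_ids = NULL,
                                     column_scales = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y have different numbers of rows")
  suff_stats(XtX = crossprod(X), XtY = crossprod(X, Y), YtY = crossprod(Y),
             n = nrow(X),
             snp_ids = snp_ids %||% colnames(X) %||%
               paste0("snp", seq_len(ncol(X))),
             column_scales = column_scales %||% rep(1, ncol(X)))
}

#' Sufficient-statistics container
#'
#' @param XtX J x J symmetric PSD matrix.
#' @param XtY J x R matrix.
#' @param YtY R x R symmetric matrix.
#' @param n Sample size (>= 2).
#' @param snp_ids Length-J SNP labels.
#' @param column_scales Length-J standardization record.
#' @return Object of class `suff_stats`.
#' @export
suff_stats <- function(XtX, XtY, YtY, n, snp_ids = NULL,
                       column_scales = NULL) {
  XtX <- as.matrix(XtX); XtY <- as.matrix(XtY); YtY <- as.matrix(YtY)
  J <- nrow(XtX); R <- ncol(XtY)
  if (!is_symmetric_tol(XtX, 1e-8)) stop("XtX must be symmetric")
  stopifnot(ncol(XtX) == J, nrow(XtY) == J, nrow(YtY) == R, ncol(YtY) == R,
            n >= 2)
  structure(list(XtX = symmetrize(XtX), XtY = XtY, YtY = symmetrize(YtY),
                 n = as.integer(n),
                 snp_ids = snp_ids %||% paste0("snp", seq_len(J)),
                 column_scales = column_scales %||% rep(1, J),
                 J = J, R = R),
            class = "suff_stats")
}
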