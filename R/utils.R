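#' @keywords internal
"_PACKAGE"

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix.
row_logsumexp <- function(X) {
  m <- apply(X, 1, max)
  m + log(rowSums(exp(X - m)))
}

# Force exact symmetry.
symmetrize <- function(A) (A + t(A)) / 2

# Project a symmetric matrix onto the PSD cone by clipping negative
# eigenvalues at zero (keeps eigenvectors).
psd_project <- function(A) {
  A <- symmetrize(A)
  e <- eigen(A, symmetric = TRUE)
  if (all(e$values >= 0)) return(A)
  lam <- pmax(e$values, 0)
  symmetrize(e$vectors %*% (lam * t(e$vectors)))
}

is_symmetric_tol <- function(A, tol = 1e-10)
  is.matrix(A) && nrow(A) == ncol(A) && max(abs(A - t(A))) <= tol * max(1, max(abs(A)))

# Minimum eigenvalue of a symmetric matrix.
min_eigval <- function(A) min(eigen(symmetrize(A), symmetric = TRUE,
                                    only.values = TRUE)$values)

# log N(x; 0, Sigma) for a positive-definite Sigma via Cholesky.
ldmvnorm0 <- function(x, Sigma) {
  Rc <- chol(Sigma)
  d <- length(x)
  q <- sum(backsolve(Rc, x, transpose = TRUE)^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(Rc))) + q)
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix, plus its rank.
sym_pinv <- function(A, tol = 1e-10) {
  e <- eigen(symmetrize(A), symmetric = TRUE)
  pos <- e$values > tol * max(e$values[1], 1)
  r <- sum(pos)
  if (r == 0) {
    pinv <- matrix(0, nrow(A), ncol(A))
  } else {
    v <- e$vectors[, pos, drop = FALSE]
    pinv <- v %*% (t(v) / e$values[pos])
  }
  list(pinv = symmetrize(pinv), rank = r)
}

# Run an expression with a temporarily seeded RNG, restoring prior state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
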