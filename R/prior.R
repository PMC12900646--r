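# Mixture-of-multivariate-normals effect-sharing prior.
#
# The prior on a single multitrait effect b (length R) is
#   g(b) = sum_k w_k N(b; 0, sigma2_0 * U_k),
# where each U_k is a (possibly singular) R x R covariance matrix encoding a
# pattern of effect sharing across traits, and the weights w_k sum to 1.

#' Construct a mixture-of-multivariate-normals effect-sharing prior
#'
#' Bundles a list of covariance components (sharing patterns) with mixture
#' weights into the prior used by [mvfine()] and [mvfine_rss()]. Each
#' component is an R x R symmetric positive-semidefinite matrix; singular
#' components (e.g. trait-specific singletons, rank-1 shared patterns) are
#' permitted and handled without ever inverting a component.
#'
#' @param components List of R x R symmetric PSD matrices, optionally named.
#' @param weights Numeric vector of mixture weights, one per component;
#'   nonnegative, normalized to sum to 1. Default: uniform.
#' @param labels Optional character vector of component labels; defaults to
#'   names of `components` or `comp1`, `comp2`, ...
#'
#' @return An object of class `mix_prior` with elements `U` (list of
#'   matrices), `w` (weights), `labels`, `R` (trait count), `K`
#'   (component count), plus cached eigendecompositions used internally.
#' @export
mix_prior <- function(components, weights = NULL, labels = NULL) {
  stopifnot(is.list(components), length(components) >= 1)
  K <- length(components)
  R <- nrow(components[[1]])
  for (k in seq_len(K)) {
    U <- components[[k]]
    if (!is_symmetric_tol(U, 1e-10))
      stop("component ", k, " is not symmetric within tolerance")
    if (nrow(U) != R)
      stop("components have inconsistent dimensions")
    if (min_eigval(U) < -1e-8)
      stop("component ", k, " is not positive semidefinite (tolerance -1e-8)")
  }
  components <- lapply(components, function(U) {
    U <- symmetrize(U)
    if (min_eigval(U) < 0) psd_project(U) else U
  })
  if (is.null(weights)) weights <- rep(1 / K, K)
  stopifnot(length(weights) == K, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  if (is.null(labels))
    labels <- names(components) %||% paste0("comp", seq_len(K))
  if (is.null(names(components))) names(components) <- labels
  eig <- lapply(components, function(U) eigen(U, symmetric = TRUE))
  structure(list(U = components, w = as.numeric(weights), labels = labels,
                 R = R, K = K, eig = eig),
            class = "mix_prior")
}

#' @export
print.mix_prior <- function(x, ...) {
  cat("mix_prior:", x$K, "components over", x$R, "traits\n")
  df <- data.frame(label = x$labels, weight = signif(x$w, 4),
                   rank = vapply(x$eig, function(e)
                     sum(e$values > 1e-10 * max(e$values[1], 1)), 0L))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Canonical effect-sharing covariance components
#'
#' The fixed library of sharing patterns used when no data-driven prior is
#' available: one trait-specific singleton per trait (effect in exactly one
#' trait), independent effects across traits (identity; the "random effects"
#' special case), equal effects in all traits (all-ones; the "fixed effects"
#' special case), and one equicorrelated pattern (unit diagonal,
#' off-diagonal rho) per entry of `het_grid`. For two traits and
#' `het_grid = c(0.25, 0.5, 0.75)` this is the canonical K = 7 prior.
#'
#' @param R Number of traits (>= 1).
#' @param het_grid Numeric vector of heterogeneity correlations in (-1, 1)
#'   for the equicorrelated components. An equicorrelation matrix is only
#'   PSD for rho > -1/(R-1); values outside that range are rejected.
#' @return Named list of R x R PSD matrices, in a fixed, stable order:
#'   singletons, identity, shared (all-ones), then equicorrelated patterns.
#' @examples
#' canonical_components(2, c(0.25, 0.5, 0.75))  # the K = 7 two-trait prior
#' @export
canonical_components <- function(R, het_grid = c(0.25, 0.5, 0.75)) {
  stopifnot(R >= 1)
  if (R == 1) return(list(single = matrix(1, 1, 1)))
  comps <- list()
  for (r in seq_len(R)) {
    U <- matrix(0, R, R)
    U[r, r] <- 1
    comps[[paste0("singleton_", r)]] <- U
  }
  comps[["independent"]] <- diag(R)
  comps[["shared_equal"]] <- matrix(1, R, R)
  for (rho in het_grid) {
    if (abs(rho) >= 1)
      stop("het_grid values must lie in (-1, 1)")
    if (rho <= -1 / (R - 1))
      stop("equicorrelation rho = ", rho, " is not positive semidefinite for R = ",
           R, " traits (requires rho > ", signif(-1 / (R - 1), 3), ")")
    U <- matrix(rho, R, R)
    diag(U) <- 1
    comps[[paste0("equicorr_", rho)]] <- U
  }
  comps
}

#' Extract strong association signals from z-score panels
#'
#' Builds the panel of strongest per-region association signals used to
#' estimate data-driven effect-sharing patterns. From each region's J x R
#' z-score matrix the SNP maximizing \eqn{\max_r |z_{jr}|} is taken, and
#' retained when that maximum is at least `threshold`.
#'
#' @param z_list A single J x R z-score matrix or a list of them (one per
#'   region).
#' @param threshold Minimum cross-trait |z| for a row to qualify (default 5).
#' @return A list of class `strong_panel` with `Z` (M x R matrix of selected
#'   rows) and `selection_rule`.
#' @export
strong_signal_panel <- function(z_list, threshold = 5) {
  if (is.matrix(z_list)) z_list <- list(z_list)
  rows <- list()
  for (Z in z_list) {
    stopifnot(is.matrix(Z))
    m <- apply(abs(Z), 1, max)
    j <- which.max(m)
    if (length(j) && m[j] >= threshold)
      rows[[length(rows) + 1]] <- Z[j, ]
  }
  Zs <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0, ncol(z_list[[1]]))
  structure(list(Z = Zs,
                 selection_rule = list(rule = "per-region max |z|",
                                       threshold = threshold)),
            class = "strong_panel")
}

#' Data-driven effect-sharing covariance components
#'
#' Estimates candidate sharing patterns from a panel of strong association
#' signals: the empirical covariance of the z-score rows, one rank-1
#' component per top principal direction, and the truncated rank-`n_pcs`
#' reconstruction. All components are symmetrized and PSD-projected
#' (negative eigenvalues clipped at zero).
#'
#' @param panel A `strong_panel` (see [strong_signal_panel()]) or an M x R
#'   matrix of strong z-score rows.
#' @param n_pcs Number of principal directions to turn into rank-1
#'   components (0 <= n_pcs <= R). `n_pcs = 0` returns only the empirical
#'   covariance.
#' @return Named list of R x R PSD matrices.
#' @export
datadriven_components <- function(panel, n_pcs = 2) {
  Z <- if (inherits(panel, "strong_panel")) panel$Z else as.matrix(panel)
  M <- nrow(Z)
  R <- ncol(Z)
  if (M < 2) stop("insufficient strong signals: need at least 2 rows, got ", M)
  stopifnot(n_pcs >= 0, n_pcs <= R)
  emp <- psd_project(crossprod(Z) / M)
  comps <- list(empirical = emp)
  if (n_pcs > 0) {
    e <- eigen(emp, symmetric = TRUE)
    for (p in seq_len(n_pcs)) {
      v <- e$vectors[, p] * sqrt(max(e$values[p], 0))
      comps[[paste0("pc_", p)]] <- tcrossprod(v)
    }
    v <- e$vectors[, seq_len(n_pcs), drop = FALSE]
    lam <- pmax(e$values[seq_len(n_pcs)], 0)
    comps[[paste0("rank", n_pcs)]] <- psd_project(v %*% (lam * t(v)))
  }
  comps
}

# Log-likelihood matrix of the zero-mean mixture model z_m ~ sum_k w_k
# N(0, S_m + U_k): returns M x K matrix of log N(z_m; 0, S_m + U_k).
ed_loglik_matrix <- function(Z, components, S_list) {
  M <- nrow(Z); K <- length(components)
  L <- matrix(0, M, K)
  same_S <- is.matrix(S_list)
  for (k in seq_len(K)) {
    if (same_S) {
      Tk <- symmetrize(S_list + components[[k]])
      Rc <- tryCatch(chol(Tk), error = function(e)
        stop("S + U_", k, " is not positive definite"))
      d <- ncol(Z)
      q <- colSums(backsolve(Rc, t(Z), transpose = TRUE)^2)
      L[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(Rc))) + q)
    } else {
      for (m in seq_len(M))
        L[m, k] <- ldmvnorm0(Z[m, ], S_list[[m]] + components[[k]])
    }
  }
  L
}

#' Fit mixture weights (and optionally covariances) by extreme deconvolution
#'
#' Zero-mean extreme deconvolution EM for the model
#' \eqn{z_m \sim \sum_k w_k N(0, S_m + U_k)}: the E-step computes component
#' responsibilities, the M-step sets each weight to its mean responsibility,
#' and (optionally) updates each covariance component to the
#' responsibility-weighted average of posterior second moments,
#' PSD-projected each iteration. The observed-data log-likelihood is
#' non-decreasing across iterations.
#'
#' @param panel A `strong_panel` or M x R matrix of z-score rows.
#' @param components List of initial R x R PSD covariance components.
#' @param S_list Sampling covariance of each row: a single R x R matrix
#'   shared by all rows (default: identity, the z-score scale) or a list of
#'   M matrices.
#' @param weights Optional initial weights (default uniform).
#' @param update_covariances If `TRUE`, run the full ED M-step updating the
#'   `U_k` as well as the weights.
#' @param max_iter,tol EM stopping rule: stop when the relative change in
#'   log-likelihood falls below `tol` or after `max_iter` iterations.
#' @return A `mix_prior` whose attributes include `loglik_trace` (the
#'   per-iteration observed-data log-likelihood). Components whose weight
#'   collapses are retained with weight ~0, not dropped.
#' @export
fit_mixture_weights <- function(panel, components, S_list = NULL,
                                weights = NULL, update_covariances = FALSE,
                                max_iter = 1000, tol = 1e-8) {
  Z <- if (inherits(panel, "strong_panel")) panel$Z else as.matrix(panel)
  M <- nrow(Z); R <- ncol(Z); K <- length(components)
  stopifnot(K >= 1, M >= 1)
  if (is.null(S_list)) S_list <- diag(R)
  if (is.matrix(S_list)) {
    if (min_eigval(S_list) < -1e-10) stop("sampling covariance S is not PSD")
  } else {
    stopifnot(length(S_list) == M)
    for (S in S_list) if (min_eigval(S) < -1e-10)
      stop("a sampling covariance S_m is not PSD")
  }
  U <- lapply(components, function(x) psd_project(as.matrix(x)))
  w <- weights %||% rep(1 / K, K)
  w <- w / sum(w)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Lmat <- ed_loglik_matrix(Z, U, S_list)
    logpost <- sweep(Lmat, 2, log(pmax(w, 1e-300)), "+")
    rowll <- row_logsumexp(logpost)
    if (any(!is.finite(rowll)))
      stop("non-finite likelihood at row ", which(!is.finite(rowll))[1])
    ll <- sum(rowll)
    gamma <- exp(logpost - rowll)
    w_new <- colMeans(gamma)
    if (update_covariances) {
      same_S <- is.matrix(S_list)
      for (k in seq_len(K)) {
        acc <- matrix(0, R, R)
        if (same_S) {
          Tk <- symmetrize(S_list + U[[k]])
          A <- solve(Tk)
          W <- U[[k]] %*% A              # posterior mean operator
          Sig1 <- symmetrize(U[[k]] - W %*% U[[k]])
          Mu <- Z %*% t(W)               # M x R posterior means
          acc <- Sig1 * sum(gamma[, k]) + crossprod(Mu, gamma[, k] * Mu)
        } else {
          for (m in seq_len(M)) {
            A <- solve(symmetrize(S_list[[m]] + U[[k]]))
            W <- U[[k]] %*% A
            mu <- drop(W %*% Z[m, ])
            Sig1 <- symmetrize(U[[k]] - W %*% U[[k]])
            acc <- acc + gamma[m, k] * (Sig1 + tcrossprod(mu))
          }
        }
        denom <- sum(gamma[, k])
        if (denom > 1e-12) U[[k]] <- psd_project(acc / denom)
      }
    }
    w <- w_new
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <=
        tol * (abs(ll_trace[it - 1]) + 1e-8)) break
  }
  names(U) <- names(components) %||% paste0("comp", seq_len(K))
  out <- mix_prior(U, weights = pmax(w, 0),
                   labels = names(U))
  attr(out, "loglik_trace") <- ll_trace
  out
}

#' Read or write a prior configuration file
#'
#' The prior configuration is a JSON document: a list of objects with fields
#' `label`, `weight` and either `matrix` (R x R rows) or `canonical` (a
#' named canonical pattern plus trait count). Numeric values are written at
#' full precision so learned priors round-trip bit-exactly.
#'
#' @param prior A `mix_prior`.
#' @param path File path.
#' @return `read_prior_config` returns a `mix_prior`;
#'   `write_prior_config` returns `path` invisibly.
#' @export
write_prior_config <- function(prior, path) {
  stopifnot(inherits(prior, "mix_prior"))
  obj <- lapply(seq_len(prior$K), function(k)
    list(label = prior$labels[k], weight = prior$w[k],
         matrix = unclass(prior$U[[k]])))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_prior_config
#' @export
read_prior_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- list(); w <- numeric(0); labels <- character(0)
  for (item in obj) {
    labels <- c(labels, item$label)
    w <- c(w, as.numeric(item$weight))
    if (!is.null(item$matrix)) {
      U <- do.call(rbind, lapply(item$matrix, function(r) as.numeric(unlist(r))))
    } else if (!is.null(item$canonical)) {
      cc <- canonical_components(as.integer(item$R),
                                 het_grid = as.numeric(item$het %||% numeric(0)))
      if (!item$canonical %in% names(cc))
        stop("unknown canonical pattern: ", item$canonical)
      U <- cc[[item$canonical]]
    } else stop("prior config entry lacks both 'matrix' and 'canonical'")
    comps[[length(comps) + 1]] <- U
  }
  names(comps) <- labels
  mix_prior(comps, weights = w, labels = labels)
}
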