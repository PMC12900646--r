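# Independent oracles used across the test suite. Deliberately written
# with direct density arithmetic (solve/determinant, explicit loops),
# sharing no code with the package's log-space/Cholesky implementation.

# Multivariate normal log density at x with mean 0, by solve + determinant.
oracle_ldmvnorm <- function(x, Sigma) {
  d <- length(x)
  -0.5 * (d * log(2 * pi) +
            as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
            drop(t(x) %*% solve(Sigma, x)))
}

# Brute-force single-effect regression: enumerate every SNP-component pair
# with direct density evaluations on the marginal statistics.
oracle_ser <- function(bhat, xtx, V, Ulist, w, pi = NULL, sigma2 = 1) {
  J <- nrow(bhat); K <- length(Ulist)
  if (is.null(pi)) pi <- rep(1 / J, J)
  like <- matrix(0, J, K)   # p(bhat_j | gamma = j, component k) (ratio vs null)
  for (j in 1:J) {
    S <- V / xtx[j]
    p0 <- exp(oracle_ldmvnorm(bhat[j, ], S))
    for (k in 1:K)
      like[j, k] <- exp(oracle_ldmvnorm(bhat[j, ], S + sigma2 * Ulist[[k]])) / p0
  }
  bf <- drop(like %*% w)
  alpha <- pi * bf / sum(pi * bf)
  list(alpha = alpha, bf = bf,
       comp_post = like * rep(w, each = J) / bf,
       lbf_model = log(sum(pi * bf)))
}

# Exact single-causal-SNP posterior from raw data, by evaluating the
# nR-dimensional marginal density of vec(Y) for every (SNP, component):
#   vec(Y) | gamma=j, k  ~  N(0, V (x) I_n + sigma2 U_k (x) x_j x_j').
oracle_enum_single_causal <- function(X, Y, V, Ulist, w, pi = NULL,
                                      sigma2 = 1) {
  n <- nrow(X); J <- ncol(X); R <- ncol(Y); K <- length(Ulist)
  if (is.null(pi)) pi <- rep(1 / J, J)
  y <- as.vector(Y)                       # stacks columns (traits)
  base <- kronecker(V, diag(n))
  ll <- matrix(0, J, K)
  for (j in 1:J) {
    xxt <- tcrossprod(X[, j])
    for (k in 1:K)
      ll[j, k] <- oracle_ldmvnorm(y, base + sigma2 * kronecker(Ulist[[k]], xxt))
  }
  lw <- sweep(ll, 2, log(w), "+")
  m <- max(lw)
  pj <- pi * rowSums(exp(lw - m))
  list(alpha = pj / sum(pj),
       log_evidence = m + log(sum(pi * rowSums(exp(lw - m)))))
}

# Vectorized radical-inverse (Halton) sequence in a given base.
oracle_halton <- function(n, base) {
  i <- seq_len(n); h <- numeric(n); f <- 1 / base
  while (any(i > 0)) {
    h <- h + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  h
}

# Importance-sampling oracle for one SNP-component Bayes factor and
# posterior moments: integrate the likelihood N(bhat; b, S) against draws
# of b from the (possibly singular) prior N(0, U). Draws come from a
# randomized quasi-Monte-Carlo (shifted Halton) point set so 1e6 draws
# estimate the moments to ~1e-4 relative accuracy.
oracle_is_moments <- function(bhat, S, U, ndraw = 1e6, seed = 1) {
  set.seed(seed)
  R <- length(bhat)
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-12 * max(abs(e$values[1]), 1)
  r <- sum(pos)
  bases <- c(2, 3, 5, 7, 11)[seq_len(r)]
  Uu <- vapply(seq_len(r), function(d)
    (oracle_halton(ndraw, bases[d]) + runif(1)) %% 1, numeric(ndraw))
  Uu <- matrix(Uu, ndraw, r)
  Uu[Uu <= 0] <- .Machine$double.eps
  Zr <- qnorm(Uu)
  Bdraw <- Zr %*% (sqrt(e$values[pos]) * t(e$vectors[, pos, drop = FALSE]))
  Sinv <- solve(S)
  D <- sweep(Bdraw, 2, bhat, "-")
  logw <- -0.5 * rowSums((D %*% Sinv) * D)
  mlw <- max(logw)
  wgt <- exp(logw - mlw)
  sw <- sum(wgt)
  mu <- colSums(wgt * Bdraw) / sw
  Dc <- sweep(Bdraw, 2, mu, "-")
  Sig <- crossprod(Dc, wgt * Dc) / sw
  ldS <- as.numeric(determinant(S)$modulus)
  lbf <- (mlw + log(mean(wgt)) - 0.5 * R * log(2 * pi) - 0.5 * ldS) -
    oracle_ldmvnorm(bhat, S)
  list(lbf = lbf, mu1 = mu, Sigma1 = Sig)
}

# Independently coded scalar (single-trait) SuSiE IBSS on sufficient
# statistics, with optional 1-D prior-variance optimization mirroring the
# package's contract (Brent over log sigma2, null-check at lbf <= 0).
oracle_scalar_susie <- function(X, y, L = 5, sigma2 = NULL, s0 = 1,
                                estimate_s0 = TRUE, max_iter = 200,
                                tol = 1e-8) {
  X <- scale(X)
  y <- y - mean(y)
  n <- nrow(X); J <- ncol(X)
  if (is.null(sigma2)) sigma2 <- var(y)
  xtx <- colSums(X^2)
  s0v <- rep(s0, L)
  mu_l <- matrix(0, L, J)      # alpha * posterior mean, per effect
  alpha_l <- matrix(1 / J, L, J)
  fitted <- rep(0, n)
  ser <- function(r, s0) {
    bhat <- drop(crossprod(X, r)) / xtx
    shat2 <- sigma2 / xtx
    lbf <- dnorm(bhat, 0, sqrt(s0 + shat2), log = TRUE) -
      dnorm(bhat, 0, sqrt(shat2), log = TRUE)
    m <- max(lbf)
    alpha <- exp(lbf - m) / sum(exp(lbf - m))
    post_var <- 1 / (1 / s0 + xtx / sigma2)
    post_mean <- post_var * xtx * bhat / sigma2
    list(alpha = alpha, mean = post_mean,
         lbf_model = m + log(mean(exp(lbf - m))))
  }
  lbf_final <- rep(0, L)
  for (it in 1:max_iter) {
    alpha_old <- alpha_l
    for (l in 1:L) {
      r_l <- y - fitted + drop(X %*% mu_l[l, ])
      if (estimate_s0) {
        f <- function(ls0) ser(r_l, exp(ls0))$lbf_model
        opt <- optimize(f, c(log(1e-8), log(1e3)), maximum = TRUE,
                        tol = 1e-4)
        s0v[l] <- if (opt$objective > 0) exp(opt$maximum) else 0
      }
      fitted <- fitted - drop(X %*% mu_l[l, ])
      if (s0v[l] > 0) {
        res <- ser(r_l, s0v[l])
        alpha_l[l, ] <- res$alpha
        mu_l[l, ] <- res$alpha * res$mean
        lbf_final[l] <- res$lbf_model
      } else {
        alpha_l[l, ] <- 1 / J
        mu_l[l, ] <- 0
        lbf_final[l] <- 0
      }
      fitted <- fitted + drop(X %*% mu_l[l, ])
    }
    if (max(abs(alpha_l - alpha_old)) < tol) break
  }
  # same reporting contract as the package: effects carry an estimated
  # scale above the floor and non-negligible single-effect evidence
  active <- s0v > 1e-9 & lbf_final > 0.1
  pip <- 1 - apply(1 - alpha_l[active, , drop = FALSE], 2, prod)
  list(alpha = alpha_l, pip = pip, s0 = s0v, lbf = lbf_final)
}

# Brute-force zero-mean extreme deconvolution EM (nested loops, linear
# scale), for weight-only updates.
oracle_ed_weights <- function(Z, Ulist, S, w0 = NULL, n_iter = 50) {
  M <- nrow(Z); K <- length(Ulist)
  w <- if (is.null(w0)) rep(1 / K, K) else w0
  for (it in 1:n_iter) {
    gam <- matrix(0, M, K)
    for (m in 1:M) {
      for (k in 1:K)
        gam[m, k] <- w[k] * exp(oracle_ldmvnorm(Z[m, ], S + Ulist[[k]]))
      gam[m, ] <- gam[m, ] / sum(gam[m, ])
    }
    w <- colMeans(gam)
  }
  w
}
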