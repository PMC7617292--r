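# Independent reference implementations used as oracles. These deliberately
# avoid the package's C++ likelihood path and its moment builders.

# Plain-R casewise multivariate-normal log-likelihood over observed entries.
ref_fiml_loglik <- function(Y, Mu, sigmas, cell = rep(1L, nrow(Y))) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    S <- sigmas[[cell[i]]][o, o, drop = FALSE]
    d <- Y[i, o] - Mu[i, o]
    ll <- ll + as.numeric(
      -0.5 * (length(o) * log(2 * pi) +
                determinant(S, logarithm = TRUE)$modulus +
                t(d) %*% solve(S, d)))
  }
  ll
}

# Complete-data MVN log-likelihood from sufficient statistics.
ref_complete_loglik <- function(Y, mu, sigma) {
  n <- nrow(Y); p <- ncol(Y)
  S <- crossprod(sweep(Y, 2L, mu)) / n
  -0.5 * n * (p * log(2 * pi) +
                as.numeric(determinant(sigma, logarithm = TRUE)$modulus) +
                sum(diag(solve(sigma, S))))
}

# Mixture-of-normals log-likelihood evaluated directly at given parameters
# (continuous indicators, shared variances, complete data).
ref_mixture_loglik <- function(X, weights, means, variances) {
  n <- nrow(X); K <- length(weights)
  comp <- matrix(0, n, K)
  for (k in seq_len(K)) {
    comp[, k] <- log(weights[k]) +
      rowSums(dnorm(X, matrix(means[k, ], n, ncol(X), byrow = TRUE),
                    matrix(sqrt(variances), n, ncol(X), byrow = TRUE),
                    log = TRUE))
  }
  mx <- apply(comp, 1L, max)
  sum(mx + log(rowSums(exp(comp - mx))))
}

# Draw latent quadratic growth trajectories directly (diagonal psi), for
# Monte-Carlo checks of implied moments.
ref_simulate_trajectories <- function(n, alpha, psi_diag, theta, rho, times) {
  k <- length(times)
  eta <- sapply(seq_along(alpha), function(j) {
    rnorm(n, alpha[j], sqrt(psi_diag[j]))
  })
  Lam <- cbind(1, times, times^2)[, seq_along(alpha), drop = FALSE]
  Theta <- outer(sqrt(theta), sqrt(theta)) *
    rho^abs(outer(seq_len(k), seq_len(k), "-"))
  eps <- matrix(rnorm(n * k), n, k) %*% chol(Theta)
  eta %*% t(Lam) + eps
}

default_indicator_frame <- function(dat) {
  dat[c(default_indicators()$name, "suicide_attempt")]
}
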