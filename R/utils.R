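`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' package functions are reproducible without clobbering the user's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Draw n rows from MVN(mu, sigma); eigen factorisation so positive
# semi-definite covariances (zero factor variances) are handled exactly.
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  e <- eigen(sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  A <- e$vectors %*% diag(sqrt(ev), p)
  sweep(matrix(stats::rnorm(n * p), n, p) %*% t(A), 2L, mu, "+")
}

# Row-wise log-sum-exp, guarding -Inf rows.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

is_binary01 <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) > 0L && all(u %in% c(0, 1))
}

# Numerical jacobian of f at x (central differences); used for delta-method
# standard errors of transformed parameters.
num_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Percentile bootstrap interval as order statistics of the draws
# ((B+1)*alpha rule, clamped to the observed range).
percentile_ci <- function(draws, level = 0.95) {
  draws <- draws[is.finite(draws)]
  B <- length(draws)
  if (B < 1L) return(c(lower = NA_real_, upper = NA_real_))
  alpha <- (1 - level) / 2
  s <- sort(draws)
  lo <- min(max(1L, floor((B + 1) * alpha)), B)
  hi <- max(min(B, ceiling((B + 1) * (1 - alpha))), 1L)
  c(lower = s[lo], upper = s[hi])
}
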