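#' Specify a latent growth curve model
#'
#' Trajectory shape and residual structure for the six-occasion symptom
#' series. Shapes nest (intercept in linear in quadratic). Residuals are a
#' single variance (`homoscedastic`), six free variances
#' (`heteroscedastic`), or six free variances with a lag-power
#' autocorrelation `Theta[j,k] = sqrt(theta_j theta_k) rho^|j-k|`
#' (`heteroscedastic_ar1`). The autocorrelation exponent is the occasion
#' lag by default; set `ar_on_months = TRUE` to use month gaps instead.
#'
#' @param shape `"intercept"`, `"linear"` or `"quadratic"`.
#' @param residuals `"homoscedastic"`, `"heteroscedastic"` or
#'   `"heteroscedastic_ar1"`.
#' @param times occasion codes in months (default `c(0,3,9,12,18,24)`).
#' @param fixed_zero factors whose variance (and covariances) are fixed to
#'   zero, a subset of `c("intercept","linear","quadratic")`.
#' @param ar_on_months exponent of `rho` uses month gaps rather than
#'   occasion lag.
#' @return object of class `growth_spec`.
#' @export
growth_spec <- function(shape = c("quadratic", "linear", "intercept"),
                        residuals = c("heteroscedastic_ar1",
                                      "heteroscedastic", "homoscedastic"),
                        times = bdi_occasions(),
                        fixed_zero = character(),
                        ar_on_months = FALSE) {
  shape <- match.arg(shape)
  residuals <- match.arg(residuals)
  d <- switch(shape, intercept = 1L, linear = 2L, quadratic = 3L)
  factors <- c("intercept", "linear", "quadratic")[seq_len(d)]
  fixed_zero <- intersect(fixed_zero, factors)
  structure(list(shape = shape, residuals = residuals, times = times,
                 d = d, factors = factors, fixed_zero = fixed_zero,
                 ar_on_months = ar_on_months),
            class = "growth_spec")
}

# Loading matrix. The quadratic column is scaled by 1/100 internally
# (months^2 reaches 576 at 24 months; unscaled columns condition the
# optimisation badly). Natural-unit parameters are recovered by the
# `growth_scale()` diagonal.
growth_lambda <- function(spec, internal = TRUE) {
  t <- spec$times
  L <- cbind(intercept = rep(1, length(t)), linear = t,
             quadratic = if (internal) t^2 / 100 else t^2)
  L[, seq_len(spec$d), drop = FALSE]
}

growth_scale <- function(spec) c(1, 1, 1 / 100)[seq_len(spec$d)]

# lag matrix for the AR exponent
growth_lag <- function(spec) {
  if (spec$ar_on_months) {
    abs(outer(spec$times, spec$times, "-"))
  } else {
    idx <- seq_along(spec$times)
    abs(outer(idx, idx, "-"))
  }
}

growth_n_theta <- function(spec) {
  if (spec$residuals == "homoscedastic") 1L else length(spec$times)
}

# ---- parameter packing ------------------------------------------------------
# packed vector: alpha (internal scale, d) | lower-triangular Cholesky of the
# free-factor covariance block (log diagonal) | log theta | atanh rho

growth_free <- function(spec) setdiff(spec$factors, spec$fixed_zero)

growth_parnames <- function(spec) {
  free <- growth_free(spec)
  df <- length(free)
  nm <- paste0("alpha_", spec$factors)
  if (df > 0L) {
    for (i in seq_len(df)) {
      for (j in seq_len(i)) {
        nm <- c(nm, paste0("Lpsi_", free[i], ".", free[j]))
      }
    }
  }
  nt <- growth_n_theta(spec)
  nm <- c(nm, if (nt == 1L) "log_theta" else paste0("log_theta_", seq_len(nt)))
  if (spec$residuals == "heteroscedastic_ar1") nm <- c(nm, "atanh_rho")
  nm
}

growth_unpack <- function(par, spec) {
  d <- spec$d
  free <- growth_free(spec)
  df <- length(free)
  pos <- d
  alpha_int <- par[seq_len(d)]
  L <- matrix(0, d, d)
  if (df > 0L) {
    fi <- match(free, spec$factors)
    for (i in seq_len(df)) {
      for (j in seq_len(i)) {
        pos <- pos + 1L
        v <- par[pos]
        L[fi[i], fi[j]] <- if (i == j) exp(v) else v
      }
    }
  }
  psi_int <- L %*% t(L)
  nt <- growth_n_theta(spec)
  theta <- exp(par[pos + seq_len(nt)])
  pos <- pos + nt
  if (nt == 1L) theta <- rep(theta, length(spec$times))
  rho <- if (spec$residuals == "heteroscedastic_ar1") tanh(par[pos + 1L]) else 0
  list(alpha_int = alpha_int, psi_int = psi_int, theta = theta, rho = rho)
}

growth_theta_matrix <- function(theta, rho, spec) {
  outer(sqrt(theta), sqrt(theta)) * rho^growth_lag(spec)
}

growth_moments_internal <- function(u, spec) {
  Lam <- growth_lambda(spec, internal = TRUE)
  mu <- drop(Lam %*% u$alpha_int)
  sigma <- Lam %*% u$psi_int %*% t(Lam) + growth_theta_matrix(u$theta, u$rho, spec)
  list(mu = mu, sigma = sigma)
}

# internal -> natural units (points, points/month, points/month^2)
growth_natural <- function(u, spec) {
  s <- growth_scale(spec)
  list(alpha = u$alpha_int * s,
       psi = diag(s, spec$d) %*% u$psi_int %*% diag(s, spec$d),
       theta = u$theta, rho = u$rho)
}

#' Model-implied moments of a latent growth curve model
#'
#' Mean `Lambda alpha` and covariance `Lambda Psi Lambda' + Theta`, with
#' `Lambda` columns `(1, t, t^2)` truncated to the shape and `Theta` built
#' from the residual variances and lag-power autocorrelation.
#'
#' @param params list with `alpha` (factor means in natural units), `psi`
#'   (d x d factor covariance), `theta` (residual variances, length 1 or 6)
#'   and `rho` (0 unless the spec is AR).
#' @param spec a [growth_spec()].
#' @return list with `mu` (length-6 mean) and `sigma` (6 x 6 covariance).
#' @export
implied_moments <- function(params, spec) {
  d <- spec$d
  psi <- as.matrix(params$psi)
  stopifnot(nrow(psi) == d, ncol(psi) == d)
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("`psi` must be positive semi-definite", call. = FALSE)
  Lam <- growth_lambda(spec, internal = FALSE)
  theta <- params$theta
  if (length(theta) == 1L) theta <- rep(theta, length(spec$times))
  rho <- params$rho %||% 0
  list(mu = drop(Lam %*% params$alpha),
       sigma = Lam %*% psi %*% t(Lam) + growth_theta_matrix(theta, rho, spec))
}

# ---- FIML machinery ---------------------------------------------------------

# Group the rows of Y (NA = missing) by (cell, missingness pattern) and
# extract fixed data blocks once, so likelihood evaluations only rebuild the
# (small) mean/covariance structures.
fiml_prepare <- function(Y, cell = rep(1L, nrow(Y))) {
  Y <- as.matrix(Y)
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0L)) {
    stop("each case must have at least one observed occasion", call. = FALSE)
  }
  key <- paste0(cell, ":", apply(obs, 1L, paste, collapse = ""))
  groups <- split(seq_len(nrow(Y)), key)
  patterns <- lapply(groups, function(rows) {
    idx <- which(obs[rows[1L], ])
    list(idx = as.integer(idx), rows = as.integer(rows),
         Y = Y[rows, idx, drop = FALSE])
  })
  list(patterns = unname(patterns),
       cell = as.integer(vapply(groups, function(r) cell[r[1L]], integer(1L))),
       n = nrow(Y), p = ncol(Y))
}

fiml_eval <- function(prep, Mu, sigmas) {
  fiml_loglik_cpp(prep$patterns, Mu, sigmas, prep$cell)
}

#' FIML log-likelihood of a growth model on observed data
#'
#' Sum over cases of the multivariate-normal log-density over each case's
#' observed subset of occasions, using the corresponding sub-vector and
#' sub-matrix of the model-implied moments. Reduces to the complete-data
#' log-likelihood when nothing is missing.
#'
#' @param params natural-unit parameter list as in [implied_moments()].
#' @param dataset `trial_dataset` (or data.frame with `bdi_m*` columns),
#'   or a numeric matrix of occasion scores with `NA` for missing.
#' @param spec a [growth_spec()].
#' @return scalar log-likelihood.
#' @export
fiml_loglik <- function(params, dataset, spec) {
  Y <- growth_outcome_matrix(dataset, spec)
  mom <- implied_moments(params, spec)
  prep <- fiml_prepare(Y)
  Mu <- matrix(mom$mu, prep$n, prep$p, byrow = TRUE)
  fiml_eval(prep, Mu, list(mom$sigma))
}

growth_outcome_matrix <- function(dataset, spec) {
  if (is.matrix(dataset)) {
    stopifnot(ncol(dataset) == length(spec$times))
    return(dataset)
  }
  cols <- paste0("bdi_m", spec$times)
  missing_cols <- setdiff(cols, names(dataset))
  if (length(missing_cols) > 0L) {
    stop("dataset lacks occasion columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as.matrix(dataset[cols])
}

growth_start <- function(Y, spec) {
  m <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Lam <- growth_lambda(spec, internal = TRUE)
  alpha <- drop(qr.solve(Lam, m))
  free <- growth_free(spec)
  df <- length(free)
  chol_par <- numeric(0)
  if (df > 0L) {
    init_sd <- c(intercept = sqrt(max(v[1L] / 2, 0.5)),
                 linear = 0.1, quadratic = 0.5)  # quadratic on internal scale
    for (i in seq_len(df)) {
      for (j in seq_len(i)) {
        chol_par <- c(chol_par, if (i == j) log(init_sd[free[i]]) else 0)
      }
    }
  }
  nt <- growth_n_theta(spec)
  ltheta <- if (nt == 1L) log(mean(v) / 2) else log(pmax(v / 2, 1e-3))
  c(alpha, chol_par, ltheta,
    if (spec$residuals == "heteroscedastic_ar1") atanh(0.1))
}

#' Fit a latent growth curve model by FIML
#'
#' Maximises the full-information likelihood by quasi-Newton optimisation
#' (`nlminb`) with variance parameters log-transformed, the factor
#' covariance parameterised through its Cholesky factor, and the AR
#' parameter tanh-transformed, so the implied covariance is positive
#' semi-definite at every iterate. The best of `n_starts` starts (a
#' moment-based start plus jittered copies) is returned. Wald tests of the
#' free factor variances are reported via delta-method standard errors;
#' variances at the effective lower bound are flagged as boundary
#' solutions (the usual caveat that variance tests at a boundary are
#' conservative applies).
#'
#' @param dataset as in [fiml_loglik()] (needs >= 10 cases).
#' @param spec a [growth_spec()].
#' @param n_starts number of optimisation starts.
#' @param seed RNG seed for start jitter.
#' @param control passed to [stats::nlminb()].
#' @return object of class `lgcm_fit`: natural-unit `alpha`, `psi`,
#'   `theta`, `rho`, standard errors, Wald variance tests, log-likelihood,
#'   parameter count, AIC/BIC, convergence information.
#' @export
fit_lgcm <- function(dataset, spec, n_starts = 5L, seed = 1L,
                     control = list(iter.max = 500L, eval.max = 1000L)) {
  Y <- growth_outcome_matrix(dataset, spec)
  if (nrow(Y) < 10L) stop("need at least 10 cases", call. = FALSE)
  prep <- fiml_prepare(Y)
  obj <- function(par) {
    u <- growth_unpack(par, spec)
    mom <- growth_moments_internal(u, spec)
    Mu <- matrix(mom$mu, prep$n, prep$p, byrow = TRUE)
    ll <- fiml_eval(prep, Mu, list(mom$sigma))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start0 <- growth_start(Y, spec)
  starts <- list(start0)
  with_seed(seed, {
    for (s in seq_len(max(0L, n_starts - 1L))) {
      starts[[s + 1L]] <- start0 + stats::rnorm(length(start0), 0, 0.3)
    }
  })
  best <- NULL
  codes <- integer(0)
  for (st in starts) {
    opt <- tryCatch(stats::nlminb(st, obj, control = control),
                    error = function(e) NULL)
    if (is.null(opt)) next
    codes <- c(codes, opt$convergence)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("optimisation failed in all starts", call. = FALSE)

  par <- best$par
  names(par) <- growth_parnames(spec)
  u <- growth_unpack(par, spec)
  nat <- growth_natural(u, spec)
  n_params <- length(par)
  ll <- -best$objective

  H <- tryCatch(stats::optimHess(par, obj), error = function(e) NULL)
  vcov_packed <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  se_nat <- wald <- NULL
  nat_fun <- function(p) {
    v <- growth_natural(growth_unpack(p, spec), spec)
    c(v$alpha, diag(v$psi), v$theta, v$rho)
  }
  nat_vec <- nat_fun(par)
  nat_names <- c(paste0("alpha_", spec$factors),
                 paste0("psi_", spec$factors),
                 paste0("theta_", seq_along(spec$times)), "rho")
  if (!is.null(vcov_packed) && all(is.finite(vcov_packed))) {
    J <- num_jacobian(nat_fun, par)
    V <- J %*% vcov_packed %*% t(J)
    se_nat <- sqrt(pmax(diag(V), 0))
  } else {
    se_nat <- rep(NA_real_, length(nat_vec))
  }
  names(nat_vec) <- names(se_nat) <- nat_names

  free <- growth_free(spec)
  psi_diag <- diag(nat$psi)
  boundary <- psi_diag[match(free, spec$factors)] < 1e-6
  wald <- data.frame(
    factor = free,
    variance = psi_diag[match(free, spec$factors)],
    se = se_nat[paste0("psi_", free)],
    boundary = boundary)
  wald$z <- ifelse(wald$se > 0, wald$variance / wald$se, NA_real_)
  wald$p <- 1 - stats::pnorm(wald$z)  # one-sided: variance > 0

  out <- list(
    spec = spec, alpha = nat$alpha, psi = nat$psi, theta = nat$theta,
    rho = nat$rho, loglik = ll, n_params = n_params,
    aic = -2 * ll + 2 * n_params, bic = -2 * ll + n_params * log(prep$n),
    n = prep$n, estimates = nat_vec, se = se_nat, wald_variances = wald,
    boundary_theta = any(nat$theta < 1e-6),
    packed = par, vcov_packed = vcov_packed,
    convergence = best$convergence, convergence_codes = codes,
    message = best$message)
  names(out$alpha) <- spec$factors
  class(out) <- "lgcm_fit"
  out
}

#' @export
print.lgcm_fit <- function(x, ...) {
  cat("Latent growth curve model (", x$spec$shape, ", ", x$spec$residuals,
      ")\n", sep = "")
  cat("  n =", x$n, " loglik =", format(x$loglik, digits = 8),
      " BIC =", format(x$bic, digits = 8), "\n")
  cat("  factor means:",
      paste(sprintf("%s = %.3f", names(x$alpha), x$alpha), collapse = ", "),
      "\n")
  if (x$spec$residuals == "heteroscedastic_ar1") {
    cat("  residual rho =", round(x$rho, 3), "\n")
  }
  invisible(x)
}

#' Compare fitted growth models
#'
#' Information-criterion table over a set of fits on identical data, with
#' likelihood-ratio tests for nested pairs (chi-square with df equal to
#' the parameter-count difference; tests involving boundary variance
#' parameters are conservative). Each fit is compared with the largest
#' model it nests within the supplied set; non-nested pairs get no LRT.
#'
#' @param ... `lgcm_fit` objects, or a single list of them.
#' @return data.frame with model descriptors, loglik, AIC, BIC and LRT
#'   columns (`lrt_vs`, `chisq`, `df`, `p`).
#' @export
compare_growth_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "lgcm_fit")) {
    fits <- fits[[1L]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1L), "lgcm_fit")))
  ns <- vapply(fits, function(f) f$n, numeric(1L))
  if (length(unique(ns)) != 1L) {
    stop("fits must be on identical data", call. = FALSE)
  }
  lab <- vapply(fits, function(f) paste0(f$spec$shape, "/", f$spec$residuals),
                character(1L))
  tab <- data.frame(
    model = lab,
    shape = vapply(fits, function(f) f$spec$shape, character(1L)),
    residuals = vapply(fits, function(f) f$spec$residuals, character(1L)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1L)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1L)),
    aic = vapply(fits, function(f) f$aic, numeric(1L)),
    bic = vapply(fits, function(f) f$bic, numeric(1L)))
  shape_rank <- c(intercept = 1L, linear = 2L, quadratic = 3L)
  resid_rank <- c(homoscedastic = 1L, heteroscedastic = 2L,
                  heteroscedastic_ar1 = 3L)
  nested_in <- function(a, b) {  # is fit a nested in fit b?
    shape_rank[a$spec$shape] <= shape_rank[b$spec$shape] &&
      resid_rank[a$spec$residuals] <= resid_rank[b$spec$residuals] &&
      all(b$spec$fixed_zero %in% c(a$spec$fixed_zero,
                                   setdiff(c("intercept", "linear", "quadratic"),
                                           a$spec$factors))) &&
      a$n_params <= b$n_params
  }
  tab$lrt_vs <- NA_character_
  tab$chisq <- tab$df <- tab$p <- NA_real_
  for (i in seq_along(fits)) {
    cand <- Filter(function(j) j != i && nested_in(fits[[i]], fits[[j]]),
                   seq_along(fits))
    if (length(cand) == 0L) next
    j <- cand[which.max(tab$n_params[cand])]
    tab$lrt_vs[i] <- lab[j]
    tab$chisq[i] <- max(0, 2 * (fits[[j]]$loglik - fits[[i]]$loglik))
    tab$df[i] <- fits[[j]]$n_params - fits[[i]]$n_params
    tab$p[i] <- if (tab$df[i] > 0) {
      stats::pchisq(tab$chisq[i], tab$df[i], lower.tail = FALSE)
    } else if (tab$df[i] == 0) 1 else NA_real_
  }
  tab
}
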