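#' Specify a latent-profile-moderated mediation model
#'
#' Structural model fitted by [fit_medmod()]: per moderator group `g`
#' (latent profile), the mediator equation
#' `M = a0_g + a_g X + gamma_M' z + e_M`, and a quadratic latent growth
#' model for the symptom series whose linear slope is the structural
#' outcome, `eta1 = beta10_g + b_g M + cprime_g X + gamma_S' z + zeta`.
#' The b-path and direct c'-path can be constrained equal across groups
#' (the default, mirroring a final model in which neither showed
#' moderation); the a-path is always group-specific. Residual variances
#' and the lag-1-power autocorrelation of the occasion residuals are
#' shared across groups.
#'
#' @param mediator,exposure column names of the mediator change score and
#'   the (binary 0/1) trial-arm indicator.
#' @param times occasion codes in months.
#' @param b_shared,cprime_shared constrain the b / c' paths equal across
#'   groups.
#' @param covariates optional covariate columns entered linearly (with
#'   group-specific coefficients) in both the mediator and the slope
#'   equation; the home-practice level enters as its single ordinal 0-3
#'   score.
#' @param B bootstrap draw count for [bootstrap_medmod()] (>= 1).
#' @param seed bootstrap seed.
#' @param stratify resample within trial-arm strata.
#' @return object of class `medmod_spec`.
#' @export
medmod_spec <- function(mediator = "delta_ffmq", exposure = "arm",
                        times = bdi_occasions(), b_shared = TRUE,
                        cprime_shared = TRUE, covariates = character(),
                        B = 1000L, seed = 1L, stratify = TRUE) {
  stopifnot(B >= 1L)
  structure(list(mediator = mediator, exposure = exposure, times = times,
                 b_shared = b_shared, cprime_shared = cprime_shared,
                 covariates = covariates, B = as.integer(B),
                 seed = as.integer(seed), stratify = stratify),
            class = "medmod_spec")
}

#' Add covariates to a mediation specification
#'
#' Returns a spec whose mediator and slope equations both include the
#' given columns as linear terms (used for sensitivity analyses adjusting
#' for home practice and antidepressant discontinuation).
#'
#' @param spec a [medmod_spec()].
#' @param covariates character vector of covariate column names.
#' @param data optional data.frame for immediate column validation.
#' @return the modified spec.
#' @export
adjust_covariates <- function(spec, covariates, data = NULL) {
  stopifnot(inherits(spec, "medmod_spec"), is.character(covariates))
  if (!is.null(data)) {
    unknown <- setdiff(covariates, names(data))
    if (length(unknown) > 0L) {
      stop("unknown covariate column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  spec$covariates <- union(spec$covariates, covariates)
  spec
}

# ---- parameter bookkeeping --------------------------------------------------
# Packed vector (full model), G groups, q covariates:
#   per group: a0, a, log sigma_m, beta00, log psi00, beta10    (6G)
#   covariates: gamma_M (G x q), gamma_S (G x q)
#   b (1 or G) | cprime (1 or G) | log sigma_slope | beta20 (x100 internal)
#   log theta (6) | atanh rho
# Reduced (total-effect) model drops the mediator block; the single shared
# slope coefficient on X is the total effect c.

medmod_info <- function(G, q, b_shared, cprime_shared, mediator = TRUE) {
  nm <- character(0)
  idx <- list()
  add <- function(tag, k) {
    s <- length(nm) + 1L
    nm <<- c(nm, if (k == 1L) tag else paste0(tag, seq_len(k)))
    seq(s, length.out = k)
  }
  if (mediator) {
    idx$a0 <- add("a0_g", G)
    idx$a <- add("a_g", G)
    idx$lsm <- add("log_sigma_m_g", G)
  }
  idx$beta00 <- add("beta00_g", G)
  idx$lpsi00 <- add("log_psi00_g", G)
  idx$beta10 <- add("beta10_g", G)
  if (q > 0L) {
    if (mediator) idx$gM <- matrix(add("gamma_M", G * q), G, q)
    idx$gS <- matrix(add("gamma_S", G * q), G, q)
  }
  if (mediator) {
    idx$b <- add(if (b_shared) "b" else "b_g", if (b_shared) 1L else G)
    idx$cp <- add(if (cprime_shared) "cprime" else "cprime_g",
                  if (cprime_shared) 1L else G)
  } else {
    idx$cp <- add("c", 1L)
  }
  idx$lss <- add("log_sigma_slope", 1L)
  idx$beta20 <- add("beta20_int", 1L)
  idx$ltheta <- add("log_theta_", 6L)
  idx$arho <- add("atanh_rho", 1L)
  list(G = G, q = q, mediator = mediator, names = nm, idx = idx,
       n_par = length(nm))
}

medmod_unpack <- function(par, info) {
  par <- unname(par)
  G <- info$G
  ex <- function(ii) {
    v <- par[ii]
    if (length(v) == 1L) rep(v, G) else v
  }
  out <- list(
    beta00 = par[info$idx$beta00],
    psi00 = exp(par[info$idx$lpsi00]),
    beta10 = par[info$idx$beta10],
    cprime = ex(info$idx$cp),
    sigma_slope = exp(par[info$idx$lss]),
    beta20 = par[info$idx$beta20] / 100,
    beta20_int = par[info$idx$beta20],
    theta = exp(par[info$idx$ltheta]),
    rho = tanh(par[info$idx$arho]))
  if (info$mediator) {
    out$a0 <- par[info$idx$a0]
    out$a <- par[info$idx$a]
    out$sigma_m <- exp(par[info$idx$lsm])
    out$b <- ex(info$idx$b)
  }
  if (info$q > 0L) {
    if (info$mediator) {
      out$gM <- matrix(par[info$idx$gM], G, info$q)
    }
    out$gS <- matrix(par[info$idx$gS], G, info$q)
  }
  out
}

# case-specific means (n x p) and per-group covariances (list of p x p)
medmod_moments <- function(pars, X, Z, gi, info, times) {
  G <- info$G
  n <- length(X)
  lam <- times
  lam2i <- times^2 / 100
  nt <- length(times)
  J <- matrix(1, nt, nt)
  lagm <- abs(outer(seq_len(nt), seq_len(nt), "-"))
  Theta <- outer(sqrt(pars$theta), sqrt(pars$theta)) * pars$rho^lagm

  covS <- if (!is.null(Z)) rowSums(Z * pars$gS[gi, , drop = FALSE]) else 0
  if (info$mediator) {
    covM <- if (!is.null(Z)) rowSums(Z * pars$gM[gi, , drop = FALSE]) else 0
    muM <- pars$a0[gi] + pars$a[gi] * X + covM
    s <- pars$beta10[gi] + pars$b[gi] * muM + pars$cprime[gi] * X + covS
  } else {
    s <- pars$beta10[gi] + pars$cprime[gi] * X + covS
  }
  MuY <- pars$beta00[gi] + outer(s, lam) +
    matrix(pars$beta20_int * lam2i, n, nt, byrow = TRUE)
  Mu <- if (info$mediator) cbind(muM, MuY) else MuY

  sigmas <- vector("list", G)
  for (g in seq_len(G)) {
    slope_var <- pars$sigma_slope^2 +
      if (info$mediator) pars$b[g]^2 * pars$sigma_m[g]^2 else 0
    SY <- pars$psi00[g] * J + slope_var * outer(lam, lam) + Theta
    if (info$mediator) {
      cmy <- pars$b[g] * pars$sigma_m[g]^2 * lam
      sigmas[[g]] <- rbind(c(pars$sigma_m[g]^2, cmy), cbind(cmy, SY))
    } else {
      sigmas[[g]] <- SY
    }
  }
  list(Mu = Mu, sigmas = sigmas)
}

medmod_start <- function(M, X, Z, Y, gi, info) {
  G <- info$G
  par <- numeric(info$n_par)
  v1 <- stats::var(Y[, 1L], na.rm = TRUE)
  vt <- apply(Y, 2L, stats::var, na.rm = TRUE)
  vt[!is.finite(vt) | vt <= 0] <- 1
  for (g in seq_len(G)) {
    sel <- gi == g
    if (info$mediator) {
      m0 <- mean(M[sel & X == 0], na.rm = TRUE)
      m1 <- mean(M[sel & X == 1], na.rm = TRUE)
      if (!is.finite(m0)) m0 <- 0
      if (!is.finite(m1)) m1 <- m0
      par[info$idx$a0[g]] <- m0
      par[info$idx$a[g]] <- m1 - m0
      sdm <- stats::sd(M[sel], na.rm = TRUE)
      par[info$idx$lsm[g]] <- log(max(sdm, 1, na.rm = TRUE))
    }
    par[info$idx$beta00[g]] <- mean(Y[sel, 1L], na.rm = TRUE)
    par[info$idx$lpsi00[g]] <- log(max(v1 / 2, 0.5))
    par[info$idx$beta10[g]] <- -0.2
  }
  par[info$idx$cp] <- 0
  if (info$mediator) par[info$idx$b] <- 0
  par[info$idx$lss] <- log(0.2)
  par[info$idx$beta20] <- 1
  par[info$idx$ltheta] <- log(pmax(vt / 2, 1e-2))
  par[info$idx$arho] <- atanh(0.1)
  par
}

medmod_extract_data <- function(dataset, labels, spec, mediator = TRUE) {
  stopifnot(length(labels) == nrow(dataset))
  X <- dataset[[spec$exposure]]
  if (is.null(X)) stop("exposure column not found: ", spec$exposure, call. = FALSE)
  if (anyNA(X) || !all(X %in% c(0, 1))) {
    stop("exposure must be complete and binary 0/1", call. = FALSE)
  }
  M <- if (mediator) {
    m <- dataset[[spec$mediator]]
    if (is.null(m)) stop("mediator column not found: ", spec$mediator,
                         call. = FALSE)
    m
  } else NULL
  cols <- paste0("bdi_m", spec$times)
  missing_cols <- setdiff(cols, names(dataset))
  if (length(missing_cols) > 0L) {
    stop("dataset lacks occasion columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  Y <- as.matrix(dataset[cols])
  Z <- NULL
  if (length(spec$covariates) > 0L) {
    unknown <- setdiff(spec$covariates, names(dataset))
    if (length(unknown) > 0L) {
      stop("unknown covariate column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    Z <- as.matrix(dataset[spec$covariates])
    for (j in seq_len(ncol(Z))) {  # mean-impute rare covariate gaps, then centre
      mj <- mean(Z[, j], na.rm = TRUE)
      Z[is.na(Z[, j]), j] <- mj
      Z[, j] <- Z[, j] - mj
    }
  }
  groups <- sort(unique(labels))
  gi <- match(labels, groups)
  list(M = M, X = as.numeric(X), Z = Z, Y = Y, gi = gi, groups = groups,
       G = length(groups))
}

medmod_optimise <- function(D, info, spec, start = NULL, n_starts = 2L,
                            seed = 1L) {
  datmat <- if (info$mediator) cbind(D$M, D$Y) else D$Y
  keep <- rowSums(!is.na(datmat)) > 0L
  if (!all(keep)) {
    datmat <- datmat[keep, , drop = FALSE]
    D$X <- D$X[keep]
    D$gi <- D$gi[keep]
    if (!is.null(D$Z)) D$Z <- D$Z[keep, , drop = FALSE]
  }
  prep <- fiml_prepare(datmat, cell = D$gi)
  cdat <- list(X = D$X,
               Z = if (is.null(D$Z)) matrix(0, length(D$X), 0L) else D$Z,
               gi = as.integer(D$gi), times = spec$times,
               patterns = prep$patterns, cell = prep$cell)
  cidx <- c(info$idx, list(mediator = info$mediator, G = info$G,
                           q = info$q))
  obj <- function(par) medmod_obj_cpp(par, cidx, cdat)$value
  grad <- function(par) medmod_obj_cpp(par, cidx, cdat)$gradient
  starts <- list()
  if (!is.null(start)) {
    starts <- list(start)
  } else {
    s0 <- medmod_start(D$M, D$X, D$Z, D$Y, D$gi, info)
    starts <- list(s0)
    if (n_starts > 1L) {
      with_seed(seed, {
        for (k in seq_len(n_starts - 1L)) {
          starts[[k + 1L]] <- s0 + stats::rnorm(length(s0), 0, 0.2)
        }
      })
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::nlminb(st, obj, gradient = grad,
                    control = list(iter.max = 1000L, eval.max = 2000L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("moderated-mediation optimisation failed", call. = FALSE)
  list(opt = best, obj = obj, D = D, n = nrow(datmat))
}

#' Fit the latent-profile-moderated mediation model
#'
#' Joint FIML fit, per moderator group, of the mediator equation and the
#' latent growth model for the symptom series (quadratic measurement
#' structure; the structural outcome is the latent linear slope). The
#' mediator and the six occasion scores form one multivariate-normal
#' vector per case, so partially observed cases contribute through their
#' observed margins. Coefficients are in the raw units of the variables.
#' Wald tests of group differences in the a-path (and in b / c' when
#' those are freely estimated) are reported from the observed-information
#' covariance; bootstrap inference for indirect effects comes from
#' [bootstrap_medmod()].
#'
#' @param dataset wide `trial_dataset` (or compatible data.frame).
#' @param labels moderator group labels, one per row (latent profile
#'   assignment from [modal_assignment()], or `true_class` in simulation
#'   work). Each group needs >= 10 cases.
#' @param spec a [medmod_spec()].
#' @param n_starts optimisation starts.
#' @param seed RNG seed for start jitter.
#' @param start optional warm-start packed parameter vector (used by the
#'   bootstrap).
#' @param hessian compute the observed-information covariance (skipped in
#'   bootstrap refits).
#' @return object of class `medmod_fit`: per-group `a`, `b`, `cprime`,
#'   indirect effects `ie`, `index` (two groups), path table with
#'   standard errors, moderation `tests`, `r2` per equation and group,
#'   disturbance parameters, loglik/AIC/BIC, convergence info.
#' @export
fit_medmod <- function(dataset, labels, spec = medmod_spec(), n_starts = 2L,
                       seed = 1L, start = NULL, hessian = TRUE) {
  D <- medmod_extract_data(dataset, labels, spec, mediator = TRUE)
  if (any(table(D$gi) < 10L)) {
    stop("each moderator group needs at least 10 cases", call. = FALSE)
  }
  q <- if (is.null(D$Z)) 0L else ncol(D$Z)
  info <- medmod_info(D$G, q, spec$b_shared, spec$cprime_shared,
                      mediator = TRUE)
  res <- medmod_optimise(D, info, spec, start = start, n_starts = n_starts,
                         seed = seed)
  par <- res$opt$par
  names(par) <- info$names
  pars <- medmod_unpack(par, info)
  G <- D$G
  ll <- -res$opt$objective

  ie <- pars$a * pars$b
  index <- if (G == 2L) ie[2L] - ie[1L] else NA_real_

  # delta-method SEs on the natural reporting scale
  rep_fun <- function(p) {
    u <- medmod_unpack(p, info)
    v <- c(u$a0, u$a, u$b, u$cprime, u$a * u$b, u$beta00, u$beta10,
           u$beta20, u$sigma_m, u$sigma_slope, sqrt(u$psi00))
    if (G == 2L) {
      v <- c(v, u$a[2L] - u$a[1L], u$b[2L] - u$b[1L],
             u$cprime[2L] - u$cprime[1L], u$a[2L] * u$b[2L] - u$a[1L] * u$b[1L])
    }
    v
  }
  rep_names <- c(paste0("a0_", seq_len(G)), paste0("a_", seq_len(G)),
                 paste0("b_", seq_len(G)), paste0("cprime_", seq_len(G)),
                 paste0("ie_", seq_len(G)), paste0("beta00_", seq_len(G)),
                 paste0("beta10_", seq_len(G)), "beta20",
                 paste0("sigma_m_", seq_len(G)), "sigma_slope",
                 paste0("sd_intercept_", seq_len(G)))
  if (G == 2L) rep_names <- c(rep_names, "a_diff", "b_diff", "cprime_diff",
                              "index")
  est <- rep_fun(par)
  names(est) <- rep_names
  se <- rep(NA_real_, length(est))
  names(se) <- rep_names
  vcov_packed <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(par, res$obj), error = function(e) NULL)
    vcov_packed <- if (!is.null(H)) {
      tryCatch(solve(H), error = function(e) NULL)
    }
    if (!is.null(vcov_packed) && all(is.finite(vcov_packed))) {
      J <- num_jacobian(rep_fun, par)
      se <- sqrt(pmax(diag(J %*% vcov_packed %*% t(J)), 0))
      names(se) <- rep_names
    }
  }
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  paths <- data.frame(term = rep_names, estimate = est, se = se, z = z,
                      p = pval, row.names = NULL)

  tests <- paths[paths$term %in% c("a_diff",
                                   if (!spec$b_shared) "b_diff",
                                   if (!spec$cprime_shared) "cprime_diff",
                                   "index"), , drop = FALSE]

  # empirical second moments of (X, Z) per group, for variance decomposition
  moments_xz <- lapply(seq_len(G), function(g) {
    sel <- D$gi == g
    W <- cbind(X = D$X[sel], D$Z[sel, , drop = FALSE])
    stats::var(W) * (sum(sel) - 1) / sum(sel)
  })

  out <- list(
    spec = spec, groups = D$groups, G = G,
    n = res$n, n_by_group = as.integer(table(D$gi)),
    a0 = pars$a0, a = pars$a, b = pars$b, cprime = pars$cprime,
    ie = setNames(ie, paste0("group", seq_len(G))), index = index,
    beta00 = pars$beta00, beta10 = pars$beta10, beta20 = pars$beta20,
    psi00 = pars$psi00, sigma_m = pars$sigma_m,
    sigma_slope = pars$sigma_slope, theta = pars$theta, rho = pars$rho,
    gamma_m = pars$gM, gamma_s = pars$gS,
    paths = paths, tests = tests, moments_xz = moments_xz,
    loglik = ll, n_params = info$n_par,
    aic = -2 * ll + 2 * info$n_par, bic = -2 * ll + info$n_par * log(res$n),
    packed = par, info = info, vcov_packed = vcov_packed,
    convergence = res$opt$convergence, message = res$opt$message)
  out$r2 <- medmod_r2(out)
  class(out) <- "medmod_fit"
  out
}

medmod_r2 <- function(fit) {
  G <- fit$G
  r2m <- r2s <- numeric(G)
  for (g in seq_len(G)) {
    S <- fit$moments_xz[[g]]
    aM <- c(fit$a[g], if (!is.null(fit$gamma_m)) fit$gamma_m[g, ])
    exp_m <- drop(t(aM) %*% S %*% aM)
    tot_m <- exp_m + fit$sigma_m[g]^2
    if (tot_m <= 0) stop("zero implied mediator variance", call. = FALSE)
    r2m[g] <- exp_m / tot_m
    # slope predictors V = (M, X, Z); Var(M) model-implied given (X, Z)
    covM_xz <- drop(S %*% aM)
    varM <- exp_m + fit$sigma_m[g]^2
    SV <- rbind(c(varM, covM_xz), cbind(covM_xz, S))
    w <- c(fit$b[g], fit$cprime[g], if (!is.null(fit$gamma_s)) fit$gamma_s[g, ])
    exp_s <- drop(t(w) %*% SV %*% w)
    tot_s <- exp_s + fit$sigma_slope^2
    if (tot_s <= 0) stop("zero implied slope variance", call. = FALSE)
    r2s[g] <- exp_s / tot_s
  }
  data.frame(group = seq_len(G), r2_mediator = r2m, r2_slope = r2s)
}

#' @export
print.medmod_fit <- function(x, ...) {
  cat("Latent-profile-moderated mediation model (", x$G, " groups, n = ",
      x$n, ")\n", sep = "")
  for (g in seq_len(x$G)) {
    cat(sprintf("  group %d: a = %.3f  b = %.4f  indirect = %.4f\n",
                g, x$a[g], x$b[g], x$ie[g]))
  }
  cat(sprintf("  c' = %.3f  index of moderated mediation = %.4f\n",
              x$cprime[1L], x$index))
  invisible(x)
}

#' Construct path coefficients directly
#'
#' Builds a minimal `medmod_fit` from given path coefficients, so
#' indirect-effect arithmetic ([conditional_indirect_effects()],
#' [moderated_mediation_index()], [projected_change()]) can be applied to
#' published coefficients as well as to fitted models.
#'
#' @param a per-group a-path coefficients (exposure to mediator).
#' @param b b-path coefficient(s) (mediator to slope); recycled across groups.
#' @param cprime optional direct-effect coefficient(s); recycled.
#' @return object of class `medmod_fit` (coefficients only).
#' @examples
#' f <- medmod_paths(a = c(5.03, 13.87), b = -0.03)
#' conditional_indirect_effects(f)
#' moderated_mediation_index(f)
#' @export
medmod_paths <- function(a, b, cprime = NA_real_) {
  G <- length(a)
  b <- rep_len(b, G)
  cprime <- rep_len(cprime, G)
  ie <- a * b
  structure(list(a = a, b = b, cprime = cprime,
                 ie = setNames(ie, paste0("group", seq_len(G))),
                 index = if (G == 2L) ie[2L] - ie[1L] else NA_real_,
                 G = G),
            class = "medmod_fit")
}

#' Conditional indirect effects
#'
#' `ie_g = a_g * b_g` per moderator group, in outcome-slope units
#' (BDI-II points per month per arm contrast).
#'
#' @param fit a `medmod_fit`.
#' @return named numeric vector of per-group indirect effects.
#' @export
conditional_indirect_effects <- function(fit) {
  stopifnot(inherits(fit, "medmod_fit"))
  setNames(fit$a * fit$b, paste0("group", seq_len(fit$G)))
}

#' Index of moderated mediation
#'
#' Difference of the conditional indirect effects across the two moderator
#' levels, `ie_2 - ie_1`; equals `(a_2 - a_1) * b` when the b-path is
#' shared. A nonzero index evidences moderated mediation.
#'
#' @param fit a `medmod_fit` with exactly two groups.
#' @return scalar index.
#' @export
moderated_mediation_index <- function(fit) {
  stopifnot(inherits(fit, "medmod_fit"))
  if (fit$G != 2L) {
    stop("the index of moderated mediation requires exactly 2 groups",
         call. = FALSE)
  }
  ie <- conditional_indirect_effects(fit)
  unname(ie[2L] - ie[1L])
}

#' Projected outcome change over a horizon
#'
#' Expected outcome change attributable to the mediated pathway over
#' `months` months: `ie * months`, in BDI-II points.
#'
#' @param ie indirect effect(s), points/month per arm contrast.
#' @param months horizon in months (>= 0).
#' @return numeric change in points.
#' @examples
#' projected_change(-0.4161, 24)  # about -10 points
#' @export
projected_change <- function(ie, months) {
  if (any(months < 0)) stop("`months` must be >= 0", call. = FALSE)
  ie * months
}

#' Total effect of the exposure on the symptom slope
#'
#' Refits the growth side without the mediator; the shared arm-to-slope
#' coefficient is the total effect `c`.
#'
#' @inheritParams fit_medmod
#' @return list with `c`, `se`, `z`, `p`, `loglik` and the reduced-model
#'   parameter vector.
#' @export
total_effect <- function(dataset, labels, spec = medmod_spec(),
                         n_starts = 2L, seed = 1L) {
  D <- medmod_extract_data(dataset, labels, spec, mediator = FALSE)
  if (any(table(D$gi) < 10L)) {
    stop("each moderator group needs at least 10 cases", call. = FALSE)
  }
  q <- if (is.null(D$Z)) 0L else ncol(D$Z)
  info <- medmod_info(D$G, q, TRUE, TRUE, mediator = FALSE)
  res <- medmod_optimise(D, info, spec, n_starts = n_starts, seed = seed)
  par <- res$opt$par
  names(par) <- info$names
  cc <- par[info$idx$cp]
  se <- NA_real_
  H <- tryCatch(stats::optimHess(par, res$obj), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) se <- sqrt(max(V[info$idx$cp, info$idx$cp], 0))
  }
  z <- cc / se
  list(c = unname(cc), se = unname(se), z = unname(z),
       p = unname(2 * stats::pnorm(-abs(z))), loglik = -res$opt$objective,
       packed = par, convergence = res$opt$convergence)
}

#' Per-group variance explained
#'
#' `R^2 = 1 - disturbance variance / model-implied total variance` for the
#' mediator equation and for the latent-slope equation, per moderator
#' group, using the within-group empirical second moments of the exposure
#' (and covariates).
#'
#' @param fit a fitted `medmod_fit` (from [fit_medmod()]).
#' @return data.frame with `group`, `r2_mediator`, `r2_slope`.
#' @export
variance_explained <- function(fit) {
  stopifnot(inherits(fit, "medmod_fit"))
  if (is.null(fit$moments_xz)) {
    stop("variance decomposition requires a fitted model", call. = FALSE)
  }
  medmod_r2(fit)
}
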