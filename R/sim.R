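#' Default baseline indicator battery
#'
#' Class-conditional means, shared SDs and instrument bounds for the
#' continuous baseline indicators used to define the latent severity
#' profiles, plus the single binary indicator (previous suicide attempt).
#' Class 2 is the higher-severity profile; separations are moderate to
#' large (0.6--0.95 pooled SD) across the battery.
#'
#' @return data.frame with columns `name`, `mean1`, `mean2`, `sd`,
#'   `lower`, `upper`, `integer` (whether the score is rounded).
#' @export
default_indicators <- function() {
  d <- read.csv(text = "name,mean1,mean2,sd,lower,upper,integer
hamd,4,7,3.5,0,NA,FALSE
mops_abuse,4,7,4,0,NA,FALSE
onset_age,26,20,8,11,NA,FALSE
n_episodes,6,9,3.5,3,NA,TRUE
last_severity,6.3,7.2,1.1,5,9,TRUE
chronicity_months,9,14,6,0,NA,FALSE
n_comorbid,0.8,1.6,1.1,0,NA,TRUE
rum_negative,18,22,4.5,NA,NA,FALSE
rum_unresolved,14,18,4.5,NA,NA,FALSE
self_blame,8,11,3.2,NA,NA,FALSE
lack_acceptance,8,10.5,3.2,NA,NA,FALSE
early_warning,5.5,4.6,1.4,NA,NA,FALSE
act_aware,25,21,5,NA,NA,FALSE
self_efficacy,30,26,5.5,NA,NA,FALSE
contentment,4.8,4.1,1,NA,NA,FALSE
joy,4.9,4.2,1,NA,NA,FALSE
relationship_sat,25,21.5,6,NA,NA,FALSE
stigmatisation,18,23,6,NA,NA,FALSE
", stringsAsFactors = FALSE)
  d
}

#' Simulation configuration for a synthetic two-arm trial
#'
#' Builds the generating model for a synthetic trial with a two-class latent
#' severity structure, an arm -> mediator effect that differs by class
#' (a-path moderation), a mediator -> latent-linear-slope effect (b-path),
#' a quadratic latent growth trajectory for the depressive-symptom outcome
#' over six occasions with heteroscedastic lag-correlated residuals, and
#' per-wave missingness at configurable retention rates.
#'
#' Defaults are calibrated to the published quantities of a large
#' MBCT-versus-maintenance-antidepressant trial: class baseline symptom
#' means 10.71 / 19.37 BDI-II points, linear slope -0.30 points/month,
#' quadratic 0.01 points/month^2, conditional a-paths 5.03 / 13.87 FFMQ
#' points, shared b-path -0.03, direct effect 0.37, follow-up retention
#' 82.1 / 69.1 / 76.4 / 68.6 / 79.3 percent. Quantities not published
#' (mixing proportion, disturbance SDs, residual structure, indicator
#' battery) are realistic defaults documented in the methods vignette.
#'
#' @param n participant count.
#' @param pi2 mixing proportion of class 2 (higher severity), in (0,1);
#'   the boundary values 0 and 1 are allowed and give a one-class model.
#' @param indicators data.frame as [default_indicators()].
#' @param binary_probs length-2 probability of previous suicide attempt per class.
#' @param alpha0_g class-specific intercept-factor mean (BDI-II points).
#' @param alpha1 linear factor mean (points/month), before structural shifts.
#' @param alpha2 quadratic factor mean (points/month^2).
#' @param psi 3x3 growth-factor covariance matrix (default: only the
#'   intercept variance is nonzero).
#' @param a0_g mediator-equation intercept per class (FFMQ points).
#' @param a_g arm -> mediator effect per class (FFMQ points).
#' @param sigma_m mediator disturbance SD.
#' @param b_g mediator -> linear-slope coefficient per class
#'   (points/month per FFMQ point); scalar recycled to both classes.
#' @param cprime_g arm -> slope direct effect per class; scalar recycled.
#' @param sigma_slope slope disturbance SD (points/month).
#' @param theta_t six residual variances (one per occasion).
#' @param rho residual autocorrelation over occasion lag, in (-1, 1).
#' @param retention_t five follow-up response probabilities (months 3, 9,
#'   12, 18, 24); baseline is never missing.
#' @param retention_ffmq response probability for the post-treatment FFMQ
#'   (the mediator's second assessment).
#' @param mar_arm,mar_bdi logit shifts of per-wave retention per unit of
#'   (centred) arm and standardized baseline BDI-II: the missingness
#'   mechanism is MAR given fully observed fields, not MCAR.
#' @param ffmq_pre_mean_g,ffmq_pre_sd baseline FFMQ total distribution per class.
#' @param qol_mean_g,qol_sd distal quality-of-life distribution per class
#'   (never used as a profile indicator).
#' @param practice_probs 2x4 matrix of home-practice level probabilities
#'   (rows: arm 0, arm 1; columns: ordinal levels 0-3).
#' @param adm_disc_prob probability of antidepressant discontinuation per arm.
#' @param seed RNG seed recorded in the configuration.
#' @return object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n = 100, seed = 1)
#' dat <- simulate_trial(cfg)
#' @export
sim_config <- function(n = 424,
                       pi2 = 0.5,
                       indicators = default_indicators(),
                       binary_probs = c(0.12, 0.38),
                       alpha0_g = c(10.71, 19.37),
                       alpha1 = -0.30,
                       alpha2 = 0.01,
                       psi = diag(c(16, 0, 0)),
                       a0_g = c(0, 0),
                       a_g = c(5.03, 13.87),
                       sigma_m = 10,
                       b_g = c(-0.03, -0.03),
                       cprime_g = c(0.37, 0.37),
                       sigma_slope = 0.12,
                       theta_t = c(10, 12, 12, 12, 12, 14),
                       rho = 0.3,
                       retention_t = c(0.821, 0.691, 0.764, 0.686, 0.793),
                       retention_ffmq = 0.821,
                       mar_arm = 0.1,
                       mar_bdi = -0.15,
                       ffmq_pre_mean_g = c(126, 118),
                       ffmq_pre_sd = 17,
                       qol_mean_g = c(60, 52),
                       qol_sd = 12,
                       practice_probs = rbind(c(0.892, 0.070, 0.028, 0.010),
                                              c(0.339, 0.280, 0.230, 0.151)),
                       adm_disc_prob = c(0.236, 0.627),
                       seed = 1L) {
  b_g <- rep_len(b_g, 2L)
  cprime_g <- rep_len(cprime_g, 2L)
  cfg <- list(
    n = as.integer(n), pi2 = pi2, indicators = indicators,
    binary_probs = binary_probs, alpha0_g = alpha0_g, alpha1 = alpha1,
    alpha2 = alpha2, psi = psi, a0_g = a0_g, a_g = a_g, sigma_m = sigma_m,
    b_g = b_g, cprime_g = cprime_g, sigma_slope = sigma_slope,
    theta_t = theta_t, rho = rho, retention_t = retention_t,
    retention_ffmq = retention_ffmq, mar_arm = mar_arm, mar_bdi = mar_bdi,
    ffmq_pre_mean_g = ffmq_pre_mean_g, ffmq_pre_sd = ffmq_pre_sd,
    qol_mean_g = qol_mean_g, qol_sd = qol_sd,
    practice_probs = practice_probs, adm_disc_prob = adm_disc_prob,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n))
  if (cfg$n < 1L) stop("`n` must be a positive participant count", call. = FALSE)
  if (cfg$pi2 < 0 || cfg$pi2 > 1) stop("`pi2` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(cfg$retention_t)) || any(cfg$retention_t < 0) ||
      any(cfg$retention_t > 1)) {
    stop("`retention_t` must be probabilities in [0, 1]", call. = FALSE)
  }
  if (length(cfg$retention_t) != 5L) {
    stop("`retention_t` must have length 5 (one per follow-up wave)", call. = FALSE)
  }
  if (length(cfg$theta_t) != 6L) stop("`theta_t` must have length 6", call. = FALSE)
  if (any(cfg$theta_t < 0)) stop("residual variances must be >= 0", call. = FALSE)
  if (cfg$sigma_m < 0 || cfg$sigma_slope < 0) {
    stop("disturbance SDs must be >= 0", call. = FALSE)
  }
  if (abs(cfg$rho) > 1) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  if (any(cfg$binary_probs < 0 | cfg$binary_probs > 1)) {
    stop("`binary_probs` must be probabilities", call. = FALSE)
  }
  ev <- eigen(cfg$psi, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("`psi` must be positive semi-definite", call. = FALSE)
  invisible(cfg)
}

#' Occasions (months) of the repeated symptom assessments
#' @return numeric vector `c(0, 3, 9, 12, 18, 24)`.
#' @export
bdi_occasions <- function() c(0, 3, 9, 12, 18, 24)

bdi_columns <- function() paste0("bdi_m", bdi_occasions())

#' Generate a synthetic trial dataset
#'
#' Draws a wide per-participant table from the generating model of a
#' [sim_config()]: latent class ~ Bernoulli(`pi2`); arm allocated exactly
#' 1:1; baseline indicators from class-conditional normals (shared SDs)
#' and a class-conditional Bernoulli; mediator
#' `delta_ffmq = a0_g + a_g * arm + N(0, sigma_m^2)`; growth factors
#' MVN(alpha_g, psi) with the linear factor shifted by
#' `b_g * delta_ffmq + cprime_g * arm` plus a `N(0, sigma_slope^2)`
#' disturbance; occasion scores
#' `eta0 + eta1 * t + eta2 * t^2 + eps` with `eps ~ MVN(0, Theta)`,
#' `Theta[j,k] = sqrt(theta_j theta_k) rho^|j-k|`. Observed BDI-II values
#' are rounded to integers and clipped to [0, 63] at the observation step
#' only; latent quantities are untouched. Follow-up missingness is then
#' applied by [apply_missingness()].
#'
#' @param config a [sim_config()].
#' @param keep_latent if TRUE, retain unclipped latent trajectory columns
#'   (`bdi_lat_m*`) and latent growth factors (`eta0`, `eta1`) for
#'   verification work.
#' @param missingness if FALSE, skip the missingness stage (complete data).
#' @return data.frame of class `trial_dataset`; one row per participant.
#' @export
simulate_trial <- function(config, keep_latent = FALSE, missingness = TRUE) {
  validate_sim_config(config)
  n <- config$n
  with_seed(config$seed, {
    cls <- 1L + stats::rbinom(n, 1L, config$pi2)
    arm <- sample(rep_len(c(0L, 1L), n))

    ind <- config$indicators
    p <- nrow(ind)
    X <- matrix(stats::rnorm(n * p), n, p)
    mu <- rbind(ind$mean1, ind$mean2)[cls, , drop = FALSE]
    X <- mu + sweep(X, 2L, ind$sd, "*")
    for (j in seq_len(p)) {
      if (!is.na(ind$lower[j])) X[, j] <- pmax(X[, j], ind$lower[j])
      if (!is.na(ind$upper[j])) X[, j] <- pmin(X[, j], ind$upper[j])
      if (ind$integer[j]) X[, j] <- round(X[, j])
    }
    colnames(X) <- ind$name
    suicide_attempt <- stats::rbinom(n, 1L, config$binary_probs[cls])
    qol <- stats::rnorm(n, config$qol_mean_g[cls], config$qol_sd)

    ffmq_pre <- stats::rnorm(n, config$ffmq_pre_mean_g[cls], config$ffmq_pre_sd)
    delta <- config$a0_g[cls] + config$a_g[cls] * arm +
      stats::rnorm(n, 0, config$sigma_m)
    ffmq_post <- ffmq_pre + delta
    delta <- ffmq_post - ffmq_pre  # exact observed-score identity

    eta <- rmvn(n, rep(0, 3L), config$psi)
    eta0 <- config$alpha0_g[cls] + eta[, 1L]
    eta1 <- config$alpha1 + eta[, 2L] +
      config$b_g[cls] * delta + config$cprime_g[cls] * arm +
      stats::rnorm(n, 0, config$sigma_slope)
    eta2 <- config$alpha2 + eta[, 3L]

    lam <- bdi_occasions()
    Theta <- outer(sqrt(config$theta_t), sqrt(config$theta_t)) *
      config$rho^abs(outer(seq_along(lam), seq_along(lam), "-"))
    eps <- rmvn(n, rep(0, 6L), Theta)
    Ylat <- outer(eta0, rep(1, 6L)) + outer(eta1, lam) + outer(eta2, lam^2) + eps
    Yobs <- pmin(pmax(round(Ylat), 0), 63)
    colnames(Yobs) <- bdi_columns()

    practice_level <- integer(n)
    for (a in 0:1) {
      i <- which(arm == a)
      practice_level[i] <- sample(0:3, length(i), replace = TRUE,
                                  prob = config$practice_probs[a + 1L, ])
    }
    adm_discontinued <- stats::rbinom(n, 1L, config$adm_disc_prob[arm + 1L])

    dat <- data.frame(id = seq_len(n), arm = arm, Yobs,
                      ffmq_pre = ffmq_pre, ffmq_post = ffmq_post,
                      delta_ffmq = delta, X, suicide_attempt = suicide_attempt,
                      qol = qol, practice_level = practice_level,
                      adm_discontinued = adm_discontinued, true_class = cls)
    if (keep_latent) {
      lat <- Ylat
      colnames(lat) <- sub("^bdi", "bdi_lat", bdi_columns())
      dat <- cbind(dat, lat, eta0 = eta0, eta1 = eta1)
    }
    if (missingness) {
      dat <- apply_missingness(dat, config$retention_t,
                               seed = config$seed + 1L,
                               mar_arm = config$mar_arm,
                               mar_bdi = config$mar_bdi,
                               retention_ffmq = config$retention_ffmq)
    }
    class(dat) <- c("trial_dataset", "data.frame")
    attr(dat, "seed") <- config$seed
    dat
  })
}

#' Apply missing-at-random follow-up missingness
#'
#' Masks each follow-up BDI-II wave independently with probability
#' `1 - retention_t[w]`; the baseline wave is never deleted. The per-case
#' retention probability is `plogis(qlogis(r_w) + mar_arm * (arm - 0.5) +
#' mar_bdi * z0)` where `z0` is the standardized baseline score, so the
#' mechanism depends only on fully observed fields (MAR). Optionally masks
#' the post-treatment FFMQ (and hence the mediator change score).
#'
#' @param dataset a `trial_dataset` data.frame.
#' @param retention_t five follow-up retention probabilities.
#' @param seed RNG seed.
#' @param mar_arm,mar_bdi logit shifts (see [sim_config()]); 0 gives MCAR.
#' @param retention_ffmq optional retention probability for `ffmq_post`;
#'   `NULL` leaves the mediator untouched.
#' @return the dataset with masked entries set to `NA` and `delta_ffmq`
#'   recomputed from the observed pre/post scores.
#' @export
apply_missingness <- function(dataset, retention_t, seed = 1L,
                              mar_arm = 0, mar_bdi = 0,
                              retention_ffmq = NULL) {
  if (length(retention_t) != 5L) {
    stop("`retention_t` must have length 5 (one per follow-up wave)", call. = FALSE)
  }
  if (any(retention_t < 0 | retention_t > 1)) {
    stop("retention probabilities must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(dataset)
  cols <- bdi_columns()[-1L]
  b0 <- dataset[[bdi_columns()[1L]]]
  z0 <- if (stats::sd(b0, na.rm = TRUE) > 0) {
    as.numeric(scale(b0))
  } else {
    rep(0, n)
  }
  z0[is.na(z0)] <- 0
  with_seed(seed, {
    for (w in seq_along(cols)) {
      r <- retention_t[w]
      pkeep <- if (r %in% c(0, 1)) rep(r, n) else {
        stats::plogis(stats::qlogis(r) + mar_arm * (dataset$arm - 0.5) +
                        mar_bdi * z0)
      }
      drop <- stats::runif(n) > pkeep
      dataset[[cols[w]]][drop] <- NA
    }
    if (!is.null(retention_ffmq)) {
      r <- retention_ffmq
      pkeep <- if (r %in% c(0, 1)) rep(r, n) else {
        stats::plogis(stats::qlogis(r) + mar_arm * (dataset$arm - 0.5) +
                        mar_bdi * z0)
      }
      drop <- stats::runif(n) > pkeep
      dataset$ffmq_post[drop] <- NA
    }
    dataset$delta_ffmq <- dataset$ffmq_post - dataset$ffmq_pre
    dataset
  })
}

#' Model-implied marginal occasion means of the generator
#'
#' Closed-form marginal mean of the latent (pre-clipping) outcome at each
#' occasion: `sum_g pi_g (alpha0_g + E[eta1|g] t + alpha2 t^2)` with
#' `E[eta1|g] = alpha1 + b_g E[M|g] + cprime_g E[arm]` and
#' `E[M|g] = a0_g + a_g E[arm]`; used as the independent oracle for
#' Monte-Carlo checks of the generator.
#'
#' @param config a [sim_config()].
#' @return numeric vector of six means.
#' @export
implied_marginal_means <- function(config) {
  lam <- bdi_occasions()
  pg <- c(1 - config$pi2, config$pi2)
  ex <- 0.5  # 1:1 allocation
  em <- config$a0_g + config$a_g * ex
  slope_g <- config$alpha1 + config$b_g * em + config$cprime_g * ex
  drop(pg %*% (outer(config$alpha0_g, rep(1, 6L)) + outer(slope_g, lam) +
                 config$alpha2 * matrix(lam^2, 2L, 6L, byrow = TRUE)))
}
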