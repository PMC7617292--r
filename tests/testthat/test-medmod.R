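# One moderately large synthetic trial, shared across the recovery checks.
# The baseline means are shifted up so trajectories stay away from the
# instrument floor: recovery is checked under the model's own assumptions,
# free of the (intentional) mild censoring of the default calibration.
big_cfg <- sim_config(n = 5000, alpha0_g = c(30.71, 39.37), seed = 101)
big_dat <- simulate_trial(big_cfg)
big_fit <- fit_medmod(big_dat, big_dat$true_class, medmod_spec(), seed = 101)

test_that("construction identities hold exactly", {
  f <- medmod_paths(a = c(2.1, -3.7), b = 0.25, cprime = 0.5)
  expect_identical(unname(conditional_indirect_effects(f)),
                   c(2.1 * 0.25, -3.7 * 0.25))
  ie <- conditional_indirect_effects(f)
  expect_identical(moderated_mediation_index(f), unname(ie[2] - ie[1]))
  # shared b: index = (a2 - a1) * b
  expect_equal(moderated_mediation_index(f), (-3.7 - 2.1) * 0.25)
  # on a fitted model the same identities hold by construction
  expect_equal(unname(big_fit$ie), big_fit$a * big_fit$b)
  expect_equal(big_fit$index, unname(big_fit$ie[2] - big_fit$ie[1]))
  # relabelling the groups flips the sign of the index
  flipped <- medmod_paths(a = rev(c(2.1, -3.7)), b = 0.25)
  expect_equal(moderated_mediation_index(flipped),
               -moderated_mediation_index(f))
  expect_error(moderated_mediation_index(medmod_paths(a = 1, b = 1)),
               "2 groups")
})

test_that("a-paths and the b-path recover the generating truth", {
  p <- big_fit$paths
  for (g in 1:2) {
    r <- p[p$term == paste0("a_", g), ]
    expect_lt(abs(r$estimate - big_cfg$a_g[g]), 3 * r$se)
  }
  rb <- p[p$term == "b_1", ]
  expect_lt(abs(rb$estimate - big_cfg$b_g[1]), 3 * rb$se)
  rc <- p[p$term == "cprime_1", ]
  expect_lt(abs(rc$estimate - big_cfg$cprime_g[1]), 4 * rc$se)
})

test_that("variance explained matches the generating closed form", {
  r2 <- variance_explained(big_fit)
  truth <- big_cfg$a_g^2 * 0.25 / (big_cfg$a_g^2 * 0.25 + big_cfg$sigma_m^2)
  # MC s.e. of the R^2 estimates at n = 5000 is below 0.02 (delta method on
  # the a-path and mediator-SD sampling error)
  expect_lt(abs(r2$r2_mediator[1] - truth[1]), 0.02)
  expect_lt(abs(r2$r2_mediator[2] - truth[2]), 0.05)
})

test_that("null b-path gives null indirect effects", {
  cfg0 <- sim_config(n = 5000, b_g = 0, seed = 103)
  d0 <- simulate_trial(cfg0)
  f0 <- fit_medmod(d0, d0$true_class, medmod_spec(), seed = 103)
  p <- f0$paths
  for (g in 1:2) {
    r <- p[p$term == paste0("ie_", g), ]
    expect_lt(abs(r$estimate), 3 * r$se)
  }
})

test_that("total effect decomposes as the mixture of mediated plus direct", {
  tot <- total_effect(big_dat, big_dat$true_class, medmod_spec(), seed = 101)
  truth_c <- sum(c(1 - big_cfg$pi2, big_cfg$pi2) *
                   (big_cfg$a_g * big_cfg$b_g + big_cfg$cprime_g))
  expect_lt(abs(tot$c - truth_c), 3 * tot$se)
})

test_that("b and c' equal the OLS estimates when slopes are observable", {
  # near-noise-free outcome: per-person growth curves are exact, so the
  # latent slope is recoverable by per-person regression and the structural
  # coefficients by ordinary least squares within group
  set.seed(105)
  n <- 400
  lab <- rep(1:2, each = n / 2)
  X <- rep_len(c(0, 1), n)
  M <- c(2, 6)[lab] * X + rnorm(n, 0, 8)
  eta1 <- 0.1 - 0.03 * M + 0.4 * X + rnorm(n, 0, 0.05)
  eta0 <- rnorm(n, 25, 2)
  t <- bdi_occasions()
  Y <- outer(eta0, rep(1, 6)) + outer(eta1, t) + 0.01 * outer(rep(1, n), t^2) +
    matrix(rnorm(n * 6, 0, 0.002), n, 6)
  d <- data.frame(arm = X, delta_ffmq = M, Y)
  names(d)[3:8] <- paste0("bdi_m", t)

  slopes <- apply(Y, 1L, function(y) coef(lm(y ~ t + I(t^2)))[["t"]])
  # warm start at the OLS solution so the near-degenerate residual scale
  # cannot stall the optimiser short of the optimum it should confirm
  info <- modmedgrowth:::medmod_info(2, 0, FALSE, FALSE, TRUE)
  st <- numeric(info$n_par)
  for (g in 1:2) {
    sel <- lab == g
    om <- coef(lm(M[sel] ~ X[sel]))
    os <- coef(lm(slopes[sel] ~ M[sel] + X[sel]))
    st[info$idx$a0[g]] <- om[1]
    st[info$idx$a[g]] <- om[2]
    st[info$idx$lsm[g]] <- log(sd(resid(lm(M[sel] ~ X[sel]))))
    st[info$idx$beta00[g]] <- mean(eta0[sel])
    st[info$idx$lpsi00[g]] <- log(var(eta0[sel]))
    st[info$idx$beta10[g]] <- os[1]
    st[info$idx$b[g]] <- os[2]
    st[info$idx$cp[g]] <- os[3]
  }
  st[info$idx$lss] <- log(0.05)
  st[info$idx$beta20] <- 1
  st[info$idx$ltheta] <- log(rep(0.002^2, 6))
  st[info$idx$arho] <- 0
  fit <- fit_medmod(d, lab, medmod_spec(b_shared = FALSE,
                                        cprime_shared = FALSE),
                    seed = 105, start = st, hessian = FALSE)
  for (g in 1:2) {
    sel <- lab == g
    ols_m <- coef(lm(M[sel] ~ X[sel]))
    ols_s <- coef(lm(slopes[sel] ~ M[sel] + X[sel]))
    expect_lt(abs(fit$a[g] - ols_m[[2]]), 1e-4)
    expect_lt(abs(fit$b[g] - ols_s[[2]]), 1e-4)
    expect_lt(abs(fit$cprime[g] - ols_s[[3]]), 1e-4)
  }
})

test_that("irrelevant covariates leave the index essentially unchanged", {
  d <- big_dat
  set.seed(107)
  d$practice_level <- sample(0:3, nrow(d), replace = TRUE)
  d$adm_discontinued <- rbinom(nrow(d), 1, 0.4)
  spec_adj <- adjust_covariates(medmod_spec(),
                                c("practice_level", "adm_discontinued"),
                                data = d)
  fit_adj <- fit_medmod(d, d$true_class, spec_adj, seed = 107)
  se_index <- big_fit$paths$se[big_fit$paths$term == "index"]
  expect_lt(abs(fit_adj$index - big_fit$index), 3 * se_index)
  # structural count: each covariate adds one coefficient per equation per
  # group (2 equations x 2 groups x 2 covariates here)
  expect_equal(fit_adj$n_params - big_fit$n_params, 8)
  expect_error(adjust_covariates(medmod_spec(), "nope", data = d), "unknown")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- sim_config(n = 200, seed = 111)
  d <- simulate_trial(cfg)
  check_grad <- function(spec, mediator) {
    D <- modmedgrowth:::medmod_extract_data(d, d$true_class, spec, mediator)
    q <- if (is.null(D$Z)) 0L else ncol(D$Z)
    info <- modmedgrowth:::medmod_info(2L, q, spec$b_shared,
                                       spec$cprime_shared, mediator)
    datmat <- if (mediator) cbind(D$M, D$Y) else D$Y
    keep <- rowSums(!is.na(datmat)) > 0
    prep <- modmedgrowth:::fiml_prepare(datmat[keep, , drop = FALSE],
                                        cell = D$gi[keep])
    cdat <- list(X = D$X[keep],
                 Z = if (q == 0) matrix(0, sum(keep), 0) else
                   D$Z[keep, , drop = FALSE],
                 gi = as.integer(D$gi[keep]), times = spec$times,
                 patterns = prep$patterns, cell = prep$cell)
    cidx <- c(info$idx, list(mediator = mediator, G = 2L, q = q))
    set.seed(113)
    p0 <- modmedgrowth:::medmod_start(D$M[keep], D$X[keep],
                                      cdat$Z, D$Y[keep, , drop = FALSE],
                                      D$gi[keep], info) +
      rnorm(info$n_par, 0, 0.05)
    r <- modmedgrowth:::medmod_obj_cpp(p0, cidx, cdat)
    fval <- function(p) modmedgrowth:::medmod_obj_cpp(p, cidx, cdat)$value
    ng <- drop(modmedgrowth:::num_jacobian(function(p) fval(p), p0))
    expect_lt(max(abs(r$gradient - ng) / (abs(ng) + 1)), 1e-5)
  }
  check_grad(medmod_spec(), mediator = TRUE)
  check_grad(medmod_spec(b_shared = FALSE, cprime_shared = FALSE),
             mediator = TRUE)
  check_grad(adjust_covariates(medmod_spec(),
                               c("practice_level", "adm_discontinued")),
             mediator = TRUE)
  check_grad(medmod_spec(), mediator = FALSE)
})

test_that("projected change is the indirect effect times the horizon", {
  expect_equal(projected_change(-0.4161, 24), -9.9864)
  expect_equal(projected_change(0, 24), 0)
  expect_equal(projected_change(-0.4161, 0), 0)
  expect_error(projected_change(-0.4, -1), ">= 0")
})
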