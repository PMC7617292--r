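test_that("implied moments match closed forms for the intercept-only model", {
  spec <- growth_spec(shape = "intercept", residuals = "homoscedastic")
  mom <- implied_moments(list(alpha = 12, psi = matrix(4, 1, 1),
                              theta = 2, rho = 0), spec)
  expect_equal(mom$mu, rep(12, 6))
  expect_equal(mom$sigma, 4 * matrix(1, 6, 6) + 2 * diag(6))
})

test_that("the implied mean at time zero is the intercept mean", {
  spec <- growth_spec()
  mom <- implied_moments(list(alpha = c(14, -0.3, 0.01),
                              psi = diag(c(16, 0.02, 0)),
                              theta = rep(10, 6), rho = 0.3), spec)
  expect_equal(mom$mu[1], 14)
  expect_error(
    implied_moments(list(alpha = c(14, -0.3, 0.01),
                         psi = diag(c(-1, 0, 0)),
                         theta = rep(10, 6), rho = 0), spec),
    "semi-definite")
})

test_that("FIML loglik reduces to the complete-data likelihood", {
  spec <- growth_spec()
  params <- list(alpha = c(15, -0.25, 0.01), psi = diag(c(16, 0.02, 0)),
                 theta = c(10, 12, 12, 12, 12, 14), rho = 0.3)
  set.seed(20)
  mom <- implied_moments(params, spec)
  Y <- matrix(rnorm(50 * 6), 50, 6) %*% chol(mom$sigma) +
    matrix(mom$mu, 50, 6, byrow = TRUE)
  ll <- fiml_loglik(params, Y, spec)
  expect_equal(ll, ref_complete_loglik(Y, mom$mu, mom$sigma), tolerance = 1e-8)
})

test_that("a single observed occasion gives the univariate normal density", {
  spec <- growth_spec(shape = "intercept", residuals = "homoscedastic")
  params <- list(alpha = 10, psi = matrix(4, 1, 1), theta = 3, rho = 0)
  Y <- matrix(c(12.5, NA, NA, NA, NA, NA), 1, 6)
  ll <- fiml_loglik(params, Y, spec)
  expect_equal(ll, dnorm(12.5, 10, sqrt(4 + 3), log = TRUE), tolerance = 1e-10)
})

test_that("FIML marginalisation agrees with numerical integration", {
  # two-occasion toy; integrate the missing coordinate out of the joint
  spec <- growth_spec(shape = "linear", residuals = "homoscedastic",
                      times = c(0, 3))
  params <- list(alpha = c(10, -0.5), psi = diag(c(4, 0.04)), theta = 2,
                 rho = 0)
  mom <- implied_moments(params, spec)
  y1 <- 11.7
  ll <- fiml_loglik(params, matrix(c(y1, NA), 1, 2), spec)
  joint <- function(y2) {
    vapply(y2, function(v) {
      d <- c(y1, v) - mom$mu
      exp(-0.5 * (2 * log(2 * pi) +
                    determinant(mom$sigma)$modulus +
                    t(d) %*% solve(mom$sigma, d)))
    }, numeric(1))
  }
  marg <- integrate(joint, -200, 200, rel.tol = 1e-10)$value
  expect_equal(ll, log(marg), tolerance = 1e-6)
})

test_that("noise-free quadratic curves are recovered exactly", {
  set.seed(22)
  n <- 60
  t <- bdi_occasions()
  eta0 <- rnorm(n, 20, 2)
  Y <- outer(eta0, rep(1, 6)) + outer(rep(-0.3, n), t) +
    outer(rep(0.01, n), t^2) + matrix(rnorm(n * 6, 0, 0.01), n, 6)
  spec <- growth_spec(shape = "quadratic", residuals = "homoscedastic",
                      fixed_zero = c("linear", "quadratic"))
  fit <- fit_lgcm(Y, spec, n_starts = 2, seed = 1)
  expect_equal(unname(fit$alpha), c(mean(eta0), -0.3, 0.01), tolerance = 1e-2)
})

test_that("the marginal slope of synthetic trials is recovered", {
  # shifted baseline keeps trajectories away from the instrument floor, so
  # clipping cannot bias the check against the closed-form generating truth
  cfg <- sim_config(n = 2000, alpha0_g = c(30.71, 39.37), seed = 24)
  d <- simulate_trial(cfg)
  truth_slope <- cfg$alpha1 +
    sum(c(1 - cfg$pi2, cfg$pi2) *
          (cfg$b_g * (cfg$a0_g + cfg$a_g * 0.5) + cfg$cprime_g * 0.5))
  fit <- fit_lgcm(d, growth_spec(), n_starts = 3, seed = 24)
  se <- fit$se["alpha_linear"]
  expect_lt(abs(fit$alpha[["linear"]] - truth_slope), 3 * se)
  # slope reported per month: implied mean change over 3 months at baseline
  mom <- implied_moments(list(alpha = fit$alpha, psi = fit$psi,
                              theta = fit$theta, rho = fit$rho),
                         growth_spec())
  expect_equal(mom$mu[2] - mom$mu[1],
               3 * fit$alpha[["linear"]] + 9 * fit$alpha[["quadratic"]],
               tolerance = 1e-8)
})

test_that("model comparison prefers the generating shape and orders logliks", {
  cfg <- sim_config(alpha0_g = c(30.71, 39.37), seed = 26)
  d <- simulate_trial(cfg)
  fits <- lapply(c("intercept", "linear", "quadratic"), function(sh) {
    fit_lgcm(d, growth_spec(shape = sh), n_starts = 2, seed = 26)
  })
  cmp <- compare_growth_models(fits)
  expect_equal(nrow(cmp), 3)
  # nesting: more parameters never fit worse (within optimizer tolerance)
  expect_true(all(diff(cmp$loglik[order(cmp$n_params)]) > -1e-4))
  expect_equal(cmp$shape[which.min(cmp$bic)], "quadratic")
  # identical model twice: LRT statistic 0 with 0 df
  cmp2 <- compare_growth_models(fits[[3]], fits[[3]])
  expect_equal(cmp2$chisq, c(0, 0))
  expect_equal(cmp2$df, c(0, 0))
})

test_that("the optimum is invariant to starting values", {
  cfg <- sim_config(n = 300, seed = 28)
  d <- simulate_trial(cfg)
  lls <- vapply(1:3, function(s) {
    fit_lgcm(d, growth_spec(), n_starts = 3, seed = s)$loglik
  }, numeric(1))
  expect_lt(diff(range(lls)), 1e-4)
})

test_that("Wald variance tests flag absent factor variances as boundary", {
  cfg <- sim_config(n = 800, alpha0_g = c(30.71, 39.37), seed = 30)
  d <- simulate_trial(cfg)
  fit <- fit_lgcm(d, growth_spec(), n_starts = 3, seed = 30)
  w <- fit$wald_variances
  expect_true(w$z[w$factor == "intercept"] > 2)  # real intercept variance
  # quadratic factor variance is zero in the generator
  expect_true(w$boundary[w$factor == "quadratic"] ||
                w$variance[w$factor == "quadratic"] < 0.01)
})
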