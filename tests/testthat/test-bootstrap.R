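test_that("percentile intervals are order statistics with known behaviour", {
  ci <- modmedgrowth:::percentile_ci(rep(1.23, 500))
  expect_equal(unname(ci), c(1.23, 1.23))  # degenerate draws collapse the CI
  set.seed(40)
  draws <- rnorm(1999)
  ci2 <- modmedgrowth:::percentile_ci(draws)
  s <- sort(draws)
  expect_equal(unname(ci2), c(s[50], s[1950]))  # (B+1)*alpha order statistics
})

test_that("bootstrap of a sample mean matches the analytic interval", {
  set.seed(42)
  x <- rnorm(50)
  B <- 2000
  draws <- vapply(seq_len(B), function(b) {
    mean(x[sample.int(50, 50, replace = TRUE)])
  }, numeric(1))
  ci <- modmedgrowth:::percentile_ci(draws)
  analytic <- mean(x) + c(-1, 1) * 1.96 / sqrt(50)
  expect_lt(abs(ci[["lower"]] - analytic[1]), 0.05)
  expect_lt(abs(ci[["upper"]] - analytic[2]), 0.05)
})

test_that("the model bootstrap is reproducible and internally consistent", {
  cfg <- sim_config(n = 300, seed = 109)
  d <- simulate_trial(cfg)
  spec <- medmod_spec(B = 40, seed = 7)
  fit <- fit_medmod(d, d$true_class, spec, hessian = FALSE)
  b1 <- suppressWarnings(bootstrap_medmod(d, d$true_class, spec, fit = fit))
  b2 <- suppressWarnings(bootstrap_medmod(d, d$true_class, spec, fit = fit))
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$draws, b2$draws)
  expect_equal(b1$n_failed, 0)
  # bounds are order statistics of the recorded draws
  for (term in b1$ci$term) {
    ci <- modmedgrowth:::percentile_ci(b1$draws[, term])
    expect_equal(b1$ci$lower[b1$ci$term == term], unname(ci["lower"]))
    expect_equal(b1$ci$upper[b1$ci$term == term], unname(ci["upper"]))
  }
  expect_true(all(b1$ci$lower <= b1$ci$upper))
  # significance flag is "zero outside the interval"
  expect_equal(b1$ci$significant,
               !(b1$ci$lower <= 0 & b1$ci$upper >= 0))
  # draws respect the construction identity ie = a * b
  expect_equal(b1$draws[, "ie_2"], b1$draws[, "a_2"] * b1$draws[, "b_2"])
  expect_equal(b1$draws[, "index"],
               b1$draws[, "ie_2"] - b1$draws[, "ie_1"])
})

test_that("a different seed gives different draws", {
  cfg <- sim_config(n = 300, seed = 109)
  d <- simulate_trial(cfg)
  fit <- fit_medmod(d, d$true_class, medmod_spec(), hessian = FALSE)
  b1 <- suppressWarnings(bootstrap_medmod(d, d$true_class, medmod_spec(),
                                          B = 10, seed = 1, fit = fit))
  b2 <- suppressWarnings(bootstrap_medmod(d, d$true_class, medmod_spec(),
                                          B = 10, seed = 2, fit = fit))
  expect_false(identical(b1$draws, b2$draws))
})
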