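make_blobs <- function(n, delta, p = 2, seed = 1) {
  # two equal clusters at 0 and delta, unit SD
  set.seed(seed)
  cls <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * p), n, p) + (cls - 1) * delta
  list(x = as.data.frame(x), cls = cls)
}

test_that("K = 1 reduces to the closed-form single-class solution", {
  b <- make_blobs(100, 0)
  fit <- fit_lpa(b$x, K = 1)
  expect_equal(unname(fit$weights), 1)
  expect_equal(unname(fit$means[1, ]), unname(colMeans(b$x)), tolerance = 1e-8)
  expect_true(all(fit$posteriors == 1))
})

test_that("well-separated clusters are recovered", {
  b <- make_blobs(500, 5)
  fit <- fit_lpa(b$x, K = 2, seed = 2)
  expect_true(all(abs(fit$means[1, ] - 0) < 0.2))
  expect_true(all(abs(fit$means[2, ] - 5) < 0.2))
  expect_true(all(abs(fit$weights - 0.5) < 0.05))
  expect_gt(mean(modal_assignment(fit$posteriors) == b$cls), 0.98)
})

test_that("reported loglik equals direct evaluation at the parameters", {
  b <- make_blobs(200, 3)
  fit <- fit_lpa(b$x, K = 2, seed = 4)
  direct <- ref_mixture_loglik(as.matrix(b$x), fit$weights, fit$means,
                               fit$variances)
  expect_equal(fit$loglik, direct, tolerance = 1e-8)
})

test_that("EM loglik is monotone and posteriors are a proper fixed point", {
  b <- make_blobs(300, 2.5)
  x <- b$x
  x[sample.int(300, 40), 1] <- NA  # missing entries: casewise likelihood
  fit <- fit_lpa(x, K = 2, seed = 6)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(abs(rowSums(fit$posteriors) - 1) < 1e-10))
  expect_equal(unname(colMeans(fit$posteriors)), unname(fit$weights),
               tolerance = 1e-3)
})

test_that("mixed continuous/binary model agrees with an mclust cross-check", {
  # continuous-only comparison: mclust EEI is the same family
  # (diagonal, class-invariant variances)
  withr::local_package("mclust")
  b <- make_blobs(300, 4, p = 3, seed = 8)
  fit <- fit_lpa(b$x, K = 2, seed = 8)
  mc <- Mclust(b$x, G = 2, modelNames = "EEI", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
  expect_equal(unname(fit$means),
               unname(t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]),
               tolerance = 0.05)
})

test_that("relative entropy matches hand-computed values and bounds", {
  n <- 50
  expect_equal(relative_entropy(matrix(1 / 3, n, 3)), 0, tolerance = 1e-12)
  hard <- cbind(rep(c(1, 0), n / 2), rep(c(0, 1), n / 2))
  expect_equal(relative_entropy(hard), 1)
  # hand calculation from the Shannon terms of the two rows
  p <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  expect_equal(relative_entropy(p), 0.4045379, tolerance = 1e-6)
  expect_error(relative_entropy(matrix(c(0.7, 0.1), 1, 2)), "sum to 1")
})

test_that("modal assignment is the row argmax with lower-index ties", {
  expect_equal(modal_assignment(matrix(c(0.9, 0.1), 1)), 1L)
  expect_equal(modal_assignment(matrix(c(0.1, 0.9), 1)), 2L)
  expect_equal(modal_assignment(matrix(c(0.5, 0.5), 1)), 1L)
  set.seed(10)
  m <- matrix(runif(3000), 1000, 3)
  m <- m / rowSums(m)
  expect_equal(modal_assignment(m),
               apply(m, 1L, which.max))
})

test_that("profile z-scores standardise by the pooled sample moments", {
  x <- data.frame(x = 10 + 2 * as.numeric(scale(1:8)))  # mean 10, sd 2 exactly
  model <- list(K = 2, means = matrix(c(7, 13), 2, 1,
                                      dimnames = list(NULL, "x")),
                probs = matrix(numeric(0), 2, 0),
                continuous = "x", binary = character(0))
  z <- profile_zscores(model, x)
  expect_equal(z$z, c(-1.5, 1.5))
  # equal class means give zero z-difference
  model$means[] <- c(10, 10)
  z2 <- profile_zscores(model, x)
  expect_equal(diff(z2$z), 0)
  expect_error(profile_zscores(model, data.frame(x = rep(1, 8))),
               "zero-variance")
})

test_that("binary indicators enter the z-score table as proportions", {
  set.seed(12)
  x <- data.frame(cont = rnorm(200), bin = rbinom(200, 1, 0.3))
  fit <- fit_lpa(x, K = 2, binary = "bin", seed = 12)
  z <- profile_zscores(fit, x)
  zb <- z[z$indicator == "bin", ]
  expect_equal(zb$type, rep("binary", 2))
  expect_equal(zb$z, (fit$probs[, "bin"] - mean(x$bin)) / sd(x$bin),
               ignore_attr = TRUE)
})

test_that("distal comparisons recover closed-form effect sizes", {
  n <- 400
  set.seed(14)
  lab <- rep(1:2, each = n / 2)
  z <- rnorm(n / 2)
  z <- (z - mean(z)) / sd(z)
  d <- data.frame(y = c(z, z + 1),           # exact pooled SD 1, diff 1
                  same = rnorm(n),
                  flag = rep(c(0, 1), n / 2))  # identical proportions
  tab <- compare_distal(d, lab, c("y", "same", "flag"))
  expect_equal(tab$estimate[tab$variable == "y"], 1, tolerance = 1e-10)
  expect_lt(abs(tab$estimate[tab$variable == "same"]), 0.3)
  expect_equal(tab$estimate[tab$variable == "flag"], 1, tolerance = 1e-10)
  expect_equal(tab$measure[tab$variable == "flag"], "odds_ratio")
  expect_error(compare_distal(d, lab, "nope"), "unknown")
  expect_error(compare_distal(d, rep(1, n), "y"), "two classes")
})

test_that("profile enumeration flags the BIC minimiser and keeps all rows", {
  b <- make_blobs(400, 4, seed = 16)
  sel <- select_profiles(b$x, K_max = 3, seed = 16)
  expect_equal(nrow(sel), 3)
  expect_equal(sel$K[sel$best_bic], 2)
  expect_true(all(diff(sel$loglik) > -1e-6))  # more classes never fit worse
})
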