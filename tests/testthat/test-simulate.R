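test_that("generation is deterministic given a seed and respects ranges", {
  cfg <- sim_config(n = 300, seed = 42)
  d1 <- simulate_trial(cfg)
  d2 <- simulate_trial(cfg)
  expect_identical(d1, d2)

  expect_setequal(unique(d1$arm), c(0L, 1L))
  expect_equal(sum(d1$arm), 150)  # exact 1:1 allocation
  bdi <- as.matrix(d1[paste0("bdi_m", bdi_occasions())])
  expect_true(all(bdi >= 0 & bdi <= 63, na.rm = TRUE))
  expect_true(all(bdi == round(bdi), na.rm = TRUE))
  expect_false(anyNA(d1$bdi_m0))  # baseline never deleted
  expect_true(all(d1$last_severity >= 5 & d1$last_severity <= 9))
  ok <- !is.na(d1$ffmq_post)
  expect_equal(d1$delta_ffmq[ok], d1$ffmq_post[ok] - d1$ffmq_pre[ok])
  expect_true(all(is.na(d1$delta_ffmq[!ok])))
})

test_that("config validation rejects invalid inputs", {
  expect_error(sim_config(n = 0), "positive")
  expect_error(sim_config(pi2 = 1.2), "pi2")
  expect_error(sim_config(retention_t = rep(0.8, 4)), "length 5")
  expect_error(sim_config(theta_t = rep(-1, 6)), ">= 0")
  expect_error(sim_config(rho = 1.5), "rho")
})

test_that("noise-free single-class limit recovers the a-path exactly", {
  cfg <- sim_config(n = 200, pi2 = 1, sigma_m = 0, seed = 5)
  d <- simulate_trial(cfg, missingness = FALSE)
  contrast <- mean(d$delta_ffmq[d$arm == 1]) - mean(d$delta_ffmq[d$arm == 0])
  expect_equal(contrast, cfg$a_g[2], tolerance = 1e-12)
})

test_that("class-2 arm contrast of the mediator matches the generating truth", {
  cfg <- sim_config(n = 50000, seed = 11)
  d <- simulate_trial(cfg, missingness = FALSE)
  d2 <- d[d$true_class == 2, ]
  n1 <- sum(d2$arm == 1); n0 <- sum(d2$arm == 0)
  contrast <- mean(d2$delta_ffmq[d2$arm == 1]) -
    mean(d2$delta_ffmq[d2$arm == 0])
  mc_se <- cfg$sigma_m * sqrt(1 / n1 + 1 / n0)
  expect_lt(abs(contrast - cfg$a_g[2]), 3 * mc_se)
})

test_that("boundary mixing proportions give single-class moments", {
  cfg <- sim_config(n = 20000, pi2 = 0, seed = 9)
  d <- simulate_trial(cfg, missingness = FALSE)
  expect_true(all(d$true_class == 1))
  # unbounded continuous indicator: class-conditional mean is the closed form
  mc_se <- 4.5 / sqrt(nrow(d))
  expect_lt(abs(mean(d$rum_negative) - 18), 3 * mc_se)
  em <- cfg$a0_g[1] + cfg$a_g[1] * 0.5
  se_m <- sqrt(cfg$sigma_m^2 + cfg$a_g[1]^2 / 4) / sqrt(nrow(d))
  expect_lt(abs(mean(d$delta_ffmq) - em), 3 * se_m)
})

test_that("latent marginal occasion means match the closed form", {
  cfg <- sim_config(n = 100000, seed = 21)
  d <- simulate_trial(cfg, keep_latent = TRUE, missingness = FALSE)
  lat <- as.matrix(d[paste0("bdi_lat_m", bdi_occasions())])
  implied <- implied_marginal_means(cfg)
  mc_se <- apply(lat, 2L, sd) / sqrt(nrow(lat))
  expect_true(all(abs(colMeans(lat) - implied) < 3 * mc_se))
})

test_that("clipping affects a small minority of observations", {
  cfg <- sim_config(n = 20000, seed = 31)
  d <- simulate_trial(cfg, keep_latent = TRUE, missingness = FALSE)
  lat <- as.matrix(d[paste0("bdi_lat_m", bdi_occasions())])
  clipped <- mean(lat < -0.5 | lat > 63.5)
  expect_lt(clipped, 0.05)
})

test_that("missingness respects boundaries and marginal retention", {
  cfg <- sim_config(n = 200, seed = 3)
  d <- simulate_trial(cfg, missingness = FALSE)

  same <- apply_missingness(d, rep(1, 5), seed = 1)
  expect_identical(as.data.frame(same), as.data.frame(d))

  gone <- apply_missingness(d, rep(0, 5), seed = 1)
  fup <- paste0("bdi_m", bdi_occasions()[-1])
  expect_true(all(is.na(as.matrix(gone[fup]))))
  expect_false(anyNA(gone$bdi_m0))

  expect_error(apply_missingness(d, rep(0.8, 3), seed = 1), "length 5")
  expect_error(apply_missingness(d, c(0.8, 0.8, 0.8, 0.8, 1.2), seed = 1),
               "\\[0, 1\\]")

  big <- simulate_trial(sim_config(n = 10000, seed = 13), missingness = FALSE)
  masked <- apply_missingness(big, c(0.821, 0.691, 0.764, 0.686, 0.793),
                              seed = 2, mar_arm = 0.1, mar_bdi = -0.15)
  obs <- mean(!is.na(masked$bdi_m3))
  se <- sqrt(0.821 * (1 - 0.821) / 10000)
  expect_lt(abs(obs - 0.821), 3 * se)
})
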