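test_that("assay simulation is deterministic and degenerates correctly", {
  cfg <- small_assay_config(seed = 11, sigma_block = 0, sigma_bio = 0,
                            method_error = no_error())
  sim <- simulate_assay(cfg)
  expect_true(all(sim$truth$p_true == 0.5))
  expect_equal(sim$observations$n_total, sim$truth$n_total_true)
  expect_equal(sim$observations$n_gfp, sim$truth$n_gfp_true)
  # same config twice: identical tables; different seed differs
  sim2 <- simulate_assay(cfg)
  expect_identical(sim, sim2)
  sim3 <- simulate_assay(small_assay_config(seed = 12, sigma_block = 0,
                                            sigma_bio = 0, method_error = no_error()))
  expect_false(identical(sim$observations$n_total, sim3$observations$n_total))
  # design dimensions
  expect_equal(nrow(sim$observations), 3 * 3 * 2 * 3 * 6)
  expect_error(simulation_config(sigma_bio = -1), ">= 0")
  expect_error(simulation_config(split_fraction = 1.2), "split_fraction")
})

test_that("empirical variance of simulated p matches the analytic prediction", {
  cfg <- simulation_config(n_blocks = 1, focal_strains = "f", competitor_strains = "c",
                           methods = "by_eye", method_error = no_error("by_eye"),
                           reps_per_cell = 1000, sigma_block = 0, sigma_bio = 1,
                           seed = 9)
  est <- fitness_estimates(simulate_assay(cfg)$observations)
  vobs <- var(est$p)
  # independent oracle: numerical integration over the logit-normal plus the
  # binomial counting term with Poisson totals
  v_ptrue <- stats::integrate(function(z) stats::plogis(z)^2 * stats::dnorm(z),
                              -10, 10)$value - 0.25
  e_pq <- stats::integrate(function(z) {
    p <- stats::plogis(z); p * (1 - p) * stats::dnorm(z)
  }, -10, 10)$value
  e_inv_n <- sum(1 / (1:600) * stats::dpois(1:600, 176))
  pred <- v_ptrue + e_pq * e_inv_n
  mc_se <- vobs * sqrt(2 / 999)
  expect_lt(abs(vobs - pred), 3 * mc_se)
})

test_that("method error model has the right limits and bias direction", {
  n_true <- rep(500L, 500)
  set.seed(33)
  g_true <- rbinom(500, n_true, 0.5)
  # all rates zero: observed = true
  obs0 <- apply_method_error(n_true, g_true, list(fp_worm_rate = 0, fn_gfp_rate = 0, miscount_sd = 0))
  expect_equal(obs0[, "n_total"], n_true)
  expect_equal(obs0[, "n_gfp"], g_true)
  # total GFP blindness
  obs1 <- apply_method_error(n_true, g_true, list(fp_worm_rate = 0, fn_gfp_rate = 1, miscount_sd = 0))
  expect_true(all(obs1[, "n_gfp"] == 0L))
  # GFP false negatives inflate the focal frequency
  obs2 <- apply_method_error(n_true, g_true, list(fp_worm_rate = 0, fn_gfp_rate = 0.1, miscount_sd = 0))
  p_obs <- (obs2[, 1] - obs2[, 2]) / obs2[, 1]
  p_true <- (n_true - g_true) / n_true
  expect_gte(mean(p_obs > p_true), 0.95)
  # invariant always holds
  obs3 <- apply_method_error(n_true, g_true, list(fp_worm_rate = 0.05, fn_gfp_rate = 0.02, miscount_sd = 0.05))
  expect_true(all(obs3[, "n_gfp"] <= obs3[, "n_total"]))
})

test_that("split simulation reproduces the quarter/three-quarter aliquot regime", {
  sp <- simulate_split_samples(simulation_config(seed = 2), n_wells = 500,
                               worms_per_well = 694)
  rec <- sp$records
  # mean aliquot sizes near 0.25 and 0.75 of 694
  se_small <- sd(rec$n_total_small) / sqrt(nrow(rec))
  se_large <- sd(rec$n_total_large) / sqrt(nrow(rec))
  expect_lt(abs(mean(rec$n_total_small) - 694 * 0.25), 3 * se_small)
  expect_lt(abs(mean(rec$n_total_large) - 694 * 0.75), 3 * se_large)
  expect_equal(rec$n_total_small + rec$n_total_large, sp$truth$n_total)
  expect_equal(rec$n_gfp_small + rec$n_gfp_large, sp$truth$n_gfp)
  # determinism
  expect_identical(sp, simulate_split_samples(simulation_config(seed = 2),
                                              n_wells = 500, worms_per_well = 694))
  # even split of huge wells: near-perfect concordance
  big <- simulate_split_samples(simulation_config(split_fraction = 0.5, seed = 4),
                                n_wells = 200, worms_per_well = 20000)
  p_s <- focal_frequency(big$records$n_total_small, big$records$n_gfp_small)
  p_l <- focal_frequency(big$records$n_total_large, big$records$n_gfp_large)
  expect_gt(cor(p_s, p_l), 0.99)
})

test_that("mean simulated p converges to the inverse-logit of mu_logci", {
  cfg <- simulation_config(n_blocks = 1, focal_strains = "f", competitor_strains = "c",
                           methods = "by_eye", method_error = no_error("by_eye"),
                           reps_per_cell = 2000, sigma_block = 0, sigma_bio = 0,
                           mu_logci = 0.8, seed = 14)
  est <- fitness_estimates(simulate_assay(cfg)$observations)
  mc_se <- sd(est$p) / sqrt(nrow(est))
  expect_lt(abs(mean(est$p) - stats::plogis(0.8)), 3 * mc_se)
})
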