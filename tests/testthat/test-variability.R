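test_that("Median-Levene statistic matches hand-worked cases and rejects bad input", {
  expect_equal(median_levene(c(2, 2, 2)), 0)
  expect_equal(median_levene(c(1, 2, 3)), 2 / 3)
  expect_equal(median_levene(c(1, 2, 3, 10)), 2.5)
  expect_error(median_levene(numeric()), "non-empty")
  expect_error(median_levene(c(1, NA)), "finite")
})

test_that("Median-Levene equals a brute-force mean |x - median| loop", {
  naive_md <- function(x) {
    s <- sort(x)
    n <- length(s)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    tot <- 0
    for (v in x) tot <- tot + abs(v - med)
    tot / n
  }
  set.seed(202)
  for (i in 1:1000) {
    x <- rnorm(sample(1:12, 1), sd = runif(1, 0.1, 10))
    expect_equal(median_levene(x), naive_md(x), tolerance = 1e-12)
  }
})

test_that("group summaries compute SD, Md, and boundary exclusions per block-group", {
  obs <- tibble::tibble(
    block_id = "b1", focal_strain = "f", competitor_strain = "c",
    method = "m", replicate_id = paste0("r", 1:3),
    n_total = c(10L, 10L, 10L), n_gfp = c(6L, 5L, 4L)  # p = 0.4, 0.5, 0.6
  )
  s <- group_summaries(obs, "p")
  expect_equal(s$mean, 0.5)
  expect_equal(s$median, 0.5)
  expect_equal(s$sd, 0.1)
  expect_equal(s$md, 0.2 / 3, tolerance = 1e-12)
  expect_equal(s$n_excluded_boundary, 0L)

  ident <- obs
  ident$n_gfp <- c(5L, 5L, 5L)
  si <- group_summaries(ident, "p")
  expect_equal(si$sd, 0)
  expect_equal(si$md, 0)

  bnd <- obs
  bnd$n_gfp <- c(0L, 5L, 4L)  # p = 1 is a log-CI boundary
  sb <- group_summaries(bnd, "log_ci")
  expect_equal(sb$n_excluded_boundary, 1L)
  expect_equal(sb$n_obs, 2L)
})

test_that("SD and Md are location invariant", {
  set.seed(7)
  x <- rnorm(20)
  expect_equal(median_levene(x), median_levene(x + 17.3))
  expect_equal(sd(x), sd(x + 17.3))
})

test_that("mean-variance diagnostics recover exact and null relationships", {
  # groups engineered so SD is an exact linear function of the mean
  mk <- function(mu, s) mu + s * c(-1, 0, 1)  # mean mu, sd s
  obs <- do.call(rbind, lapply(1:6, function(i) {
    mu <- 100 + 20 * i
    vals <- round(mk(mu, 2 * i))
    tibble::tibble(block_id = paste0("b", i), focal_strain = "f",
                   competitor_strain = "c", method = "m",
                   replicate_id = paste0("r", 1:3),
                   n_total = 1000L, n_gfp = 1000L - as.integer(vals))
  }))
  d <- mean_variance_diagnostics(obs)
  r_p_sd <- d$correlations$r[d$correlations$metric == "p" &
                               d$correlations$variability_measure == "sd"]
  expect_equal(r_p_sd, 1, tolerance = 1e-9)
  expect_error(mean_variance_diagnostics(obs[1:6, ]), "at least 3 groups")
})

test_that("binomial SE and aliquot SE ratio follow their closed forms", {
  expect_equal(binomial_se(0.5, 100), 0.05)
  expect_equal(binomial_se(0, 50), 0)
  expect_equal(binomial_se(0.553, 143), 0.0416, tolerance = 1e-3)
  expect_error(binomial_se(0.5, 0), ">= 1")
  expect_equal(se_ratio(143, 551), sqrt(551 / 143))
  expect_equal(se_ratio(100, 100), 1)
  expect_equal(se_ratio(1, 4), 2)
  expect_error(se_ratio(0, 10), ">= 1")
  # reciprocal property
  set.seed(3)
  a <- sample(1:1000, 20); b <- sample(1:1000, 20)
  expect_equal(se_ratio(a, b) * se_ratio(b, a), rep(1, 20))
})

test_that("variance decomposition separates binomial and biological variance", {
  # identical p, huge n: biological ~ 0
  obs <- tibble::tibble(n_total = rep(100000L, 10), n_gfp = rep(50000L, 10))
  vd <- variance_decomposition(obs)
  expect_equal(vd$biological, 0)
  expect_lt(vd$total, 1e-6)
  expect_error(variance_decomposition(obs[1:2, ]), ">= 3 plates")

  # recovery of a known biological variance on the p scale (n = 500)
  set.seed(404)
  sig_p <- 0.03
  ests <- replicate(200, {
    p_true <- pmin(pmax(rnorm(24, 0.5, sig_p), 0.01), 0.99)
    n <- rpois(24, 500)
    g <- n - rbinom(24, n, p_true)
    variance_decomposition(tibble::tibble(n_total = n, n_gfp = g))$biological_raw
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - sig_p^2), 3 * mc_se)

  # zero biological variance: ratio below 0.5 in >= 90% of simulations
  hits <- replicate(200, {
    n <- rpois(24, 500)
    g <- n - rbinom(24, n, 0.5)
    variance_decomposition(tibble::tibble(n_total = n, n_gfp = g))$ratio < 0.5
  })
  expect_gte(mean(hits), 0.9)
})

test_that("log-CI component estimator returns coherent moments", {
  sim <- simulate_assay(simulation_config(n_blocks = 2, reps_per_cell = 12,
                                          sigma_block = 0, sigma_bio = 0.5,
                                          method_error = no_error(), seed = 5))
  e <- estimate_logci_components(sim$observations)
  expect_gt(e$sigma_bio, 0.3)
  expect_lt(e$sigma_bio, 0.7)
  expect_lt(abs(e$mu_logci), 0.2)
  expect_gt(e$technical_var, 0)
})
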