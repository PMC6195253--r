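test_that("model specs enforce marginality and report structure", {
  expect_s3_class(vm_spec("y", fixed = c("a", "b", "a:b")), "vm_spec")
  expect_error(vm_spec("y", fixed = c("a", "a:b")), "marginal")
  expect_error(vm_spec("y", random = c("b1", "b2")), "one random intercept")
  sp <- vm_spec("y", fixed = "method", resid_group = "pooled")
  expect_length(sp$resid_group, 0)
})

test_that("REML and ML match closed forms in the intercept-only model", {
  set.seed(21)
  y <- rnorm(20, 5, 2)
  d <- data.frame(y = y)
  fr <- fit_varmodel(vm_spec("y"), d, "REML")
  expect_equal(unname(fr$sigma2), var(y), tolerance = 1e-6)
  expect_equal(unname(fr$beta), mean(y), tolerance = 1e-6)
  # closed-form REML log-likelihood (error-contrast convention, as in base R)
  n <- length(y)
  logL_reml <- -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(var(y)) + (n - 1) + log(n))
  expect_equal(fr$logLik, logL_reml, tolerance = 1e-6)
  expect_equal(fr$logLik, as.numeric(logLik(lm(y ~ 1), REML = TRUE)), tolerance = 1e-6)
  fm <- fit_varmodel(vm_spec("y"), d, "ML")
  expect_equal(unname(fm$sigma2), var(y) * (n - 1) / n, tolerance = 1e-6)
  logL_ml <- -0.5 * (n * log(2 * pi) + n * log(var(y) * (n - 1) / n) + n)
  expect_equal(fm$logLik, logL_ml, tolerance = 1e-6)
})

test_that("two free-variance groups recover per-group sample variances and REML logL", {
  set.seed(22)
  d <- data.frame(y = c(rnorm(9, 0, 1), rnorm(14, 2, 3)),
                  g = rep(c("a", "b"), c(9, 14)))
  f <- fit_varmodel(vm_spec("y", fixed = "g", resid_group = "g"), d, "REML")
  s2 <- as.numeric(tapply(d$y, d$g, var))
  expect_equal(unname(f$sigma2), s2, tolerance = 1e-6)
  # closed form (error-contrast convention): at the optimum each group
  # contributes n_g log s_g^2 + (n_g - 1) to the deviance plus the
  # log |X' V^-1 X| adjustment; in the cell-means basis that is
  # sum log(n_g / s_g^2), and any other full-rank coding X = Xm T shifts
  # the restricted likelihood by the constant -log|T| (REML's known
  # dependence on the fixed-effect parameterization)
  ng <- as.numeric(table(d$g))
  n <- sum(ng)
  logL_cellmeans <- -0.5 * ((n - 2) * log(2 * pi) + sum(ng * log(s2)) +
                              sum(ng - 1) + sum(log(ng / s2)))
  Xm <- model.matrix(~ 0 + g, d)
  X <- f$design$X
  jac <- 0.5 * (determinant(crossprod(X))$modulus -
                  determinant(crossprod(Xm))$modulus)
  expect_equal(f$logLik, logL_cellmeans - as.numeric(jac), tolerance = 1e-6)
})

test_that("profiled likelihood matches a dense multivariate-Gaussian evaluation", {
  set.seed(23)
  d <- data.frame(
    y = rnorm(18),
    m = rep(c("x", "y", "z"), 6),
    block_id = rep(paste0("b", 1:3), each = 6)
  )
  for (crit in c("REML", "ML")) {
    f <- fit_varmodel(vm_spec("y", fixed = "m", random = "block_id", resid_group = "m"),
                      d, crit)
    # brute force: build V densely from the fitted variance parameters
    G <- 3
    v <- exp(f$theta[1:G])
    s2b <- exp(f$theta[G + 1])
    grp <- as.integer(factor(d$m))
    Z <- stats::model.matrix(~ 0 + block_id, d)
    V <- diag(v[grp]) + s2b * Z %*% t(Z)
    X <- f$design$X
    Vi <- solve(V)
    B <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
    r <- d$y - X %*% B
    quad <- drop(t(r) %*% Vi %*% r)
    n <- nrow(d); p <- ncol(X)
    dense <- if (crit == "REML") {
      -0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus + quad +
                determinant(t(X) %*% Vi %*% X)$modulus)
    } else {
      -0.5 * (n * log(2 * pi) + determinant(V)$modulus + quad)
    }
    expect_equal(f$logLik, as.numeric(dense), tolerance = 1e-6)
  }
})

test_that("AICc follows its closed form and penalizes useless parameters", {
  fake <- list(logLik = -10, k = 2, n = 10)
  expect_equal(aicc(fake), 20 + 4 + 12 / 7, tolerance = 1e-10)
  expect_equal(aicc(list(logLik = -10, k = 0, n = 10)), 20)
  expect_warning(aicc(list(logLik = -10, k = 9, n = 10)), "undefined")
  # nested ML fits: extra parameter never lowers -2 logL but can raise AICc
  set.seed(24)
  d <- data.frame(y = rnorm(30), g = rep(c("a", "b"), 15))
  f0 <- fit_varmodel(vm_spec("y"), d, "ML")
  f1 <- fit_varmodel(vm_spec("y", fixed = "g"), d, "ML")
  expect_gte(f1$logLik, f0$logLik - 1e-8)
  expect_gt(f1$aicc, f0$aicc)  # g is pure noise here
})

test_that("Satterthwaite denominator df equals the Welch formula for two groups", {
  set.seed(25)
  for (i in 1:5) {
    n1 <- sample(6:15, 1); n2 <- sample(6:15, 1)
    d <- data.frame(y = c(rnorm(n1, 0, runif(1, 0.5, 2)), rnorm(n2, 1, runif(1, 0.5, 3))),
                    g = rep(c("a", "b"), c(n1, n2)))
    f <- fit_varmodel(vm_spec("y", fixed = "g", resid_group = "g"), d, "REML")
    ft <- type3_f_test(f, "g")
    wt <- t.test(y ~ g, data = d)
    expect_equal(ft$f_value, unname(wt$statistic)^2, tolerance = 1e-6)
    expect_equal(ft$denom_df, unname(wt$parameter), tolerance = 1e-4)
    expect_equal(ft$p_value, wt$p.value, tolerance = 1e-5)
  }
})

test_that("pooled-variance balanced layout reproduces textbook one-way ANOVA", {
  set.seed(26)
  d <- data.frame(y = rnorm(24, rep(c(0, 0.5, 1), each = 8)),
                  g = rep(c("a", "b", "c"), each = 8))
  f <- fit_varmodel(vm_spec("y", fixed = "g"), d, "REML")
  ft <- type3_f_test(f, "g")
  an <- anova(lm(y ~ g, data = d))
  expect_equal(ft$f_value, an$`F value`[1], tolerance = 1e-6)
  expect_equal(ft$num_df, 2L)
  expect_equal(ft$denom_df, 21, tolerance = 1e-3)
  expect_equal(ft$p_value, an$`Pr(>F)`[1], tolerance = 1e-5)
})

test_that("group variances are recovered across simulation replicates", {
  set.seed(27)
  sig <- c(a = 1, b = 2, c = 3)
  ests <- replicate(200, {
    d <- data.frame(y = rnorm(150, 0, rep(sig, each = 50)),
                    g = rep(names(sig), each = 50))
    sqrt(fit_varmodel(vm_spec("y", fixed = "g", resid_group = "g"), d, "REML")$sigma2)
  })
  for (i in 1:3) {
    mc_se <- sd(ests[i, ]) / sqrt(ncol(ests))
    expect_lt(abs(mean(ests[i, ]) - sig[i]), 3 * mc_se)
  }
})

test_that("AICc is invariant to observation order and factor relabeling", {
  set.seed(28)
  d <- data.frame(y = rnorm(36, rep(c(0, 1, 2), 12)),
                  g = rep(c("ctl", "mid", "high"), 12))
  sp <- vm_spec("y", fixed = "g", resid_group = "g")
  a1 <- fit_varmodel(sp, d, "ML")$aicc
  a2 <- fit_varmodel(sp, d[sample(nrow(d)), ], "ML")$aicc
  expect_equal(a1, a2, tolerance = 1e-7)
  relab <- d
  relab$g <- c(ctl = "zzz", mid = "aaa", high = "mmm")[d$g]
  a3 <- fit_varmodel(sp, relab, "ML")$aicc
  expect_equal(a1, a3, tolerance = 1e-7)
})

test_that("model search ranks stably, uses the right criterion, and flags failures", {
  set.seed(29)
  d <- data.frame(y = rnorm(40), g = rep(c("a", "b"), 20))
  sp <- vm_spec("y", fixed = "g")
  ms <- model_search(d, list(sp, sp))
  expect_equal(ms$results$candidate, c(1L, 2L))  # tie keeps input order
  expect_equal(ms$results$aicc[1], ms$results$aicc[2], tolerance = 1e-6)
  expect_equal(unique(ms$results$criterion), "REML")  # same fixed set
  ms2 <- model_search(d, list(vm_spec("y"), sp))
  expect_equal(unique(ms2$results$criterion), "ML")   # differing fixed sets
  # a candidate that cannot fit (a singleton variance group) is flagged, not dropped
  d2 <- d; d2$h <- c("solo", rep(c("a", "b"), length.out = 39))
  bad <- vm_spec("y", fixed = character(), resid_group = "h")
  ms3 <- model_search(d2, list(sp, bad))
  expect_equal(nrow(ms3$results), 2L)
  expect_false(ms3$results$converged[ms3$results$rank == 2])
})

test_that("block random intercepts pin to zero at the boundary without error", {
  cfg <- simulation_config(n_blocks = 4, reps_per_cell = 8, sigma_block = 0,
                           method_error = no_error(), seed = 3)
  est <- fitness_estimates(simulate_assay(cfg)$observations)
  f <- fit_varmodel(vm_spec("p", fixed = "method", random = "block_id",
                            resid_group = "method"), est, "REML")
  expect_equal(f$sigma2_block, 0)
  expect_true(all(f$sigma2 > 0))
})

test_that("the SD-of-log-CI analysis runs end to end and rejects degenerate designs", {
  sim <- simulate_assay(small_assay_config(seed = 31))
  ana <- analyze_sd_logci(sim$observations)
  expect_true("method" %in% ana$best_spec$fixed)
  expect_equal(ana$f_test_method$num_df, 2L)
  expect_gt(ana$f_test_method$p_value, 0)
  expect_equal(nrow(ana$search_variance), 3L)
  single <- sim$observations[sim$observations$method == "by_eye", ]
  expect_error(analyze_sd_logci(single), "single level")
})

test_that("the focal-frequency analysis handles a block missing one method", {
  sim <- simulate_assay(small_assay_config(seed = 32))
  obs <- sim$observations
  drop <- obs$block_id == "block1" & obs$method == "by_eye"
  ana <- analyze_p(obs[!drop, ])
  expect_equal(ana$f_test_method$num_df, 2L)
  expect_true(is.finite(ana$f_test_method$denom_df))
  expect_equal(ana$fit$criterion, "REML")
})
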