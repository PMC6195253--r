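#!/usr/bin/env Rscript
# The headline question: do the three counting methods differ in mean focal
# frequency or in variability? Fits heteroscedastic linear models with
# AICc-guided pooling and tests the method effect by type-III F with
# Satterthwaite degrees of freedom.

library(compfit)

obs <- read_observations("results/observations.csv")

cat("== Variability scale: SD of log(CI) per block-group ==\n")
ana_sd <- analyze_sd_logci(obs)
cat("Residual-variance grouping search (REML AICc):\n")
print(as.data.frame(ana_sd$search_variance[, c("label", "aicc", "delta_aicc", "rank")]),
      row.names = FALSE)
cat("Fixed-effect ladder at the chosen grouping (ML AICc):\n")
print(as.data.frame(ana_sd$search_fixed[, c("label", "aicc", "delta_aicc", "rank")]),
      row.names = FALSE)
ft <- ana_sd$f_test_method
cat(sprintf("Method effect on SD_log(CI): F(%d, %.1f) = %.2f, P = %.3f\n\n",
            ft$num_df, ft$denom_df, ft$f_value, ft$p_value))

cat("== Mean scale: replicate-level p with a block random intercept ==\n")
ana_p <- analyze_p(obs)
ftp <- ana_p$f_test_method
cat(sprintf("Method effect on p: F(%d, %.1f) = %.2f, P = %.3f\n",
            ftp$num_df, ftp$denom_df, ftp$f_value, ftp$p_value))
cat(sprintf("Block variance component: %.2e\n", ana_p$fit$sigma2_block))

report <- function(ana) list(
  best_spec = list(fixed = ana$best_spec$fixed, random = ana$best_spec$random,
                   resid_group = ana$best_spec$resid_group),
  residual_variances = as.list(ana$fit$sigma2),
  block_variance = ana$fit$sigma2_block,
  logLik = ana$fit$logLik, aicc = ana$fit$aicc,
  search_variance = ana$search_variance, search_fixed = ana$search_fixed,
  f_test_method = as.list(ana$f_test_method[1, ])
)
jsonlite::write_json(list(sd_logci = report(ana_sd), p = report(ana_p)),
                     "results/method_comparison.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("\nWrote results/method_comparison.json\n")
cat("Under the generator's mild method-error defaults, neither scale shows a\n")
cat("significant method effect at the study's design size, matching the\n")
cat("motivation for adopting automated counting.\n")
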