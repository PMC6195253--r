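#' Median-Levene dispersion statistic
#'
#' Mean absolute deviation of a sample from its median,
#' `Md = (1/n) * sum(|x_i - median(x)|)`. A robust dispersion measure used to
#' compare variability between groups whose means may differ; for even sample
#' sizes the median is the midpoint of the two central order statistics.
#'
#' @param values Numeric vector, at least one finite value.
#' @return Non-negative scalar; 0 iff every value equals the sample median.
#' @examples
#' median_levene(c(1, 2, 3))      # 2/3
#' median_levene(c(1, 2, 3, 10))  # 2.5
#' @export
median_levene <- function(values) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  mean(abs(values - stats::median(values)))
}

#' Within-block group summaries of a fitness estimator
#'
#' Summarizes one fitness metric per (focal strain, competitor strain, method,
#' block) cell: number of defined observations, mean, median, sample SD
#' (n - 1 denominator), and the Median-Levene statistic. Boundary-undefined
#' values (`ci` at p = 1; `log_ci` at p in {0, 1}; any p from an empty sample)
#' are excluded from the summaries and counted in `n_excluded_boundary`.
#'
#' @param observations Plate-observation table (columns `block_id`,
#'   `focal_strain`, `competitor_strain`, `method`, `n_total`, `n_gfp`).
#' @param metric One of `"p"`, `"ci"`, `"log_ci"`.
#' @param log_base Passed to [fitness_estimates()].
#' @return A tibble with one row per group: key columns, `metric`, `n_obs`,
#'   `mean`, `median`, `sd` (`NA` and flagged when fewer than 2 defined
#'   values), `md`, `n_excluded_boundary`, `sd_defined`.
#' @export
group_summaries <- function(observations, metric = c("p", "ci", "log_ci"),
                            log_base = exp(1)) {
  metric <- match.arg(metric)
  est <- fitness_estimates(observations, log_base = log_base)
  est$.value <- est[[metric]]
  out <- est |>
    dplyr::group_by(.data$focal_strain, .data$competitor_strain,
                    .data$method, .data$block_id) |>
    dplyr::summarise(
      metric = metric,
      n_obs = sum(!is.na(.data$.value)),
      mean = mean(.data$.value, na.rm = TRUE),
      median = stats::median(.data$.value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$.value)) >= 2) stats::sd(.data$.value, na.rm = TRUE) else NA_real_,
      md = if (sum(!is.na(.data$.value)) >= 1) {
        median_levene(.data$.value[!is.na(.data$.value)])
      } else NA_real_,
      n_excluded_boundary = sum(is.na(.data$.value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(sd_defined = !is.na(.data$sd), mean = ifelse(is.nan(.data$mean), NA_real_, .data$mean))
  tibble::as_tibble(out)
}

#' Mean-variance diagnostics across the three fitness estimators
#'
#' Measures of variability are often correlated with the mean, which confounds
#' comparisons of variance between groups whose means differ. This diagnostic
#' computes, for each estimator (p, CI, log(CI)), the Pearson correlation of
#' the group mean with the group SD and with the group Median-Levene statistic
#' over all block-groups pooled, plus the scatter data behind the six panels
#' (3 metrics x 2 variability measures).
#'
#' @param observations Plate-observation table.
#' @param log_base Passed to [fitness_estimates()].
#' @return A list with `correlations` (tibble: metric, variability_measure,
#'   r, n_groups) and `scatter` (per-group means vs SD and Md, long format).
#' @export
mean_variance_diagnostics <- function(observations, log_base = exp(1)) {
  metrics <- c("p", "ci", "log_ci")
  summaries <- dplyr::bind_rows(lapply(metrics, function(m) {
    group_summaries(observations, metric = m, log_base = log_base)
  }))
  scatter <- summaries |>
    dplyr::filter(!is.na(.data$mean)) |>
    tidyr::pivot_longer(cols = c("sd", "md"), names_to = "variability_measure",
                        values_to = "variability") |>
    dplyr::filter(!is.na(.data$variability)) |>
    dplyr::select("metric", "focal_strain", "competitor_strain", "method",
                  "block_id", "mean", "variability_measure", "variability")
  correlations <- scatter |>
    dplyr::group_by(.data$metric, .data$variability_measure) |>
    dplyr::summarise(
      r = stats::cor(.data$mean, .data$variability),
      n_groups = dplyr::n(),
      .groups = "drop"
    )
  if (any(correlations$n_groups < 3)) {
    stop("mean-variance diagnostics need at least 3 groups per metric", call. = FALSE)
  }
  list(correlations = tibble::as_tibble(correlations),
       scatter = tibble::as_tibble(scatter))
}

#' Binomial standard error of a proportion
#'
#' The sampling (technical) SE of an estimated proportion from counting `n`
#' worms: `sqrt(p * (1 - p) / n)`.
#'
#' @param p Proportion in `[0, 1]`.
#' @param n Number of worms counted; at least 1.
#' @return Non-negative numeric.
#' @examples
#' binomial_se(0.5, 100)
#' @export
binomial_se <- function(p, n) {
  check_proportion(p)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  sqrt(p * (1 - p) / n)
}

#' Ratio of binomial standard errors for two sample sizes
#'
#' At a common underlying proportion, the SE of the smaller sample exceeds
#' that of the larger by `sqrt(n_large / n_small)`. For the aliquot sizes 143
#' and 551 this is about 1.96, i.e. roughly 2.
#'
#' @param n_small,n_large Positive counts.
#' @return `sqrt(n_large / n_small)`.
#' @examples
#' se_ratio(143, 551)
#' @export
se_ratio <- function(n_small, n_large) {
  if (any(n_small < 1) || any(n_large < 1)) stop("counts must be >= 1", call. = FALSE)
  sqrt(n_large / n_small)
}

#' Moment estimates of the log-CI mean and biological SD from plate counts
#'
#' Companion to [variance_decomposition()] on the log-odds scale. The
#' counting (technical) variance of `log(CI)` from a binomial sample of
#' `n` worms is `1/(n p (1 - p))` by the delta method; subtracting its mean
#' from the within-block among-plate variance of `log(CI)` leaves a moment
#' estimate of the biological variance on the log-CI scale. Block effects
#' are removed by centring within blocks (with the usual within-group
#' degrees-of-freedom correction), so the estimate targets the among-plate,
#' within-block biological SD.
#'
#' @param observations Plate-observation table (one focal/competitor/method
#'   group, or any set believed to share a common mean structure per block).
#' @return A list: `mu_logci` (grand mean of defined log CI), `sigma_bio`
#'   (floored at 0), `sigma_bio_raw_sq` (unfloored moment estimate),
#'   `technical_var`, `n_plates`, `n_excluded_boundary`.
#' @export
estimate_logci_components <- function(observations) {
  est <- fitness_estimates(observations)
  ok <- !is.na(est$log_ci)
  n_excl <- sum(!ok)
  est <- est[ok, , drop = FALSE]
  if (nrow(est) < 3) stop("need >= 3 plates with defined log CI", call. = FALSE)
  technical <- mean(1 / (est$n_total * est$p * (1 - est$p)))
  blocks <- factor(est$block_id)
  centred <- est$log_ci - stats::ave(est$log_ci, blocks)
  df <- nrow(est) - nlevels(blocks)
  within_var <- sum(centred^2) / df
  raw <- within_var - technical
  list(
    mu_logci = mean(est$log_ci),
    sigma_bio = sqrt(max(0, raw)),
    sigma_bio_raw_sq = raw,
    technical_var = technical,
    n_plates = nrow(est),
    n_excluded_boundary = n_excl
  )
}

#' Technical versus biological variance decomposition for one group of plates
#'
#' The among-plate variance of the focal frequency mixes binomial counting
#' (technical) variance with true biological variation among plates. The
#' moment decomposition used here: technical variance is the mean over plates
#' of `p(1-p)/n_total`; biological variance is the among-plate sample variance
#' of `p` minus the technical part, floored at zero (the unfloored moment
#' estimate is also reported).
#'
#' @param observations Plate-observation table for a single
#'   focal/competitor/method group; at least 3 plates with `n_total > 0`.
#' @return A list: `technical`, `biological` (floored), `biological_raw`
#'   (unfloored), `total` (among-plate variance of p), `ratio`
#'   (biological/technical), `n_plates`.
#' @export
variance_decomposition <- function(observations) {
  est <- fitness_estimates(observations)
  est <- est[!is.na(est$p) & est$n_total > 0, , drop = FALSE]
  if (nrow(est) < 3) stop("variance decomposition needs >= 3 plates with defined p", call. = FALSE)
  technical <- mean(est$p * (1 - est$p) / est$n_total)
  total <- stats::var(est$p)
  biological_raw <- total - technical
  biological <- max(0, biological_raw)
  list(
    technical = technical,
    biological = biological,
    biological_raw = biological_raw,
    total = total,
    ratio = biological / technical,
    n_plates = nrow(est)
  )
}
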