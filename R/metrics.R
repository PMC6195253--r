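#' Frequency of the focal type from dual-channel counts
#'
#' In a dual-label competition assay the total worm count comes from the
#' brightfield channel and the competitor count from the GFP channel, so the
#' focal (unmarked) frequency is the difference between the two counts divided
#' by the total.
#'
#' @param n_total Integer vector of total worms counted (brightfield). Must be
#'   at least 1.
#' @param n_gfp Integer vector of fluorescent (competitor) worms counted.
#'   Recycled against `n_total`; must satisfy `0 <= n_gfp <= n_total`.
#' @return Numeric vector of focal frequencies `p = (n_total - n_gfp)/n_total`.
#' @examples
#' focal_frequency(176, 77)
#' @export
focal_frequency <- function(n_total, n_gfp) {
  if (length(n_total) == 0L || length(n_gfp) == 0L) {
    stop("`n_total` and `n_gfp` must be non-empty", call. = FALSE)
  }
  pair <- vctrs_recycle(n_total, n_gfp)
  n_total <- pair[[1L]]
  n_gfp <- pair[[2L]]
  check_counts(n_total, n_gfp)
  if (any(n_total == 0)) {
    stop("`n_total` must be >= 1: a sample with zero counted worms has no defined focal frequency",
         call. = FALSE)
  }
  (n_total - n_gfp) / n_total
}

# minimal common-length recycling (scalar against vector), base-R style
vctrs_recycle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx == ny) return(list(x, y))
  if (nx == 1L) return(list(rep(x, ny), y))
  if (ny == 1L) return(list(x, rep(y, nx)))
  stop("count vectors must have equal length (or length 1)", call. = FALSE)
}

check_counts <- function(n_total, n_gfp) {
  if (any(!is.finite(n_total)) || any(!is.finite(n_gfp))) {
    stop("counts must be finite", call. = FALSE)
  }
  if (any(n_total < 0) || any(n_gfp < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  bad <- which(n_gfp > n_total)
  if (length(bad)) {
    stop("data-integrity error: n_gfp > n_total at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Competitive index (odds of sampling a focal worm)
#'
#' The competitive index is the odds `CI = p/(1 - p)` that a randomly sampled
#' worm is the focal type. At `p = 1` the odds are infinite; that boundary is
#' returned as `NA` (an explicit undefined flag) rather than `Inf` so that
#' downstream summaries can count exclusions.
#'
#' @param p Numeric vector of focal frequencies in `[0, 1]`.
#' @return Numeric vector `p/(1 - p)`, with `NA` at `p = 1`.
#' @examples
#' competitive_index(c(0.5, 0.75, 0))
#' @export
competitive_index <- function(p) {
  check_proportion(p)
  out <- p / (1 - p)
  out[p == 1] <- NA_real_
  out
}

#' Log competitive index (log-odds of the focal type)
#'
#' @param p Numeric vector of focal frequencies.
#' @param base Logarithm base; default natural log, the standard scale for
#'   log-odds. Use `base = 10` for decimal log-odds.
#' @return `log(p/(1-p))` in the requested base; `NA` (undefined-at-boundary
#'   flag) where `p` is 0 or 1. Downstream analyses must exclude and report
#'   these.
#' @examples
#' log_competitive_index(c(0.5, 0.75, 0.25))
#' @export
log_competitive_index <- function(p, base = exp(1)) {
  check_proportion(p)
  out <- ifelse(p > 0 & p < 1, log(p / (1 - p), base = base), NA_real_)
  as.numeric(out)
}

check_proportion <- function(p) {
  if (any(is.finite(p) & (p < 0 | p > 1))) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Compare the focal frequency of two strains against a shared competitor
#'
#' Two comparisons are in common use and easily conflated: the ratio of focal
#' proportions `p_i/p_j`, and the ratio of the corresponding odds
#' `CI_i/CI_j = (p_i/(1-p_i)) / (p_j/(1-p_j))`. Both are returned, labelled
#' distinctly.
#'
#' @param p_i,p_j Focal frequencies of strains i and j (each against the same
#'   competitor strain). `p_j` must be positive for the proportion ratio; the
#'   odds-ratio branch is additionally undefined (`NA`) where either `p` is 1.
#' @return A tibble with columns `proportion_ratio` and `odds_ratio`.
#' @examples
#' focal_odds_comparison(0.75, 0.5)
#' @export
focal_odds_comparison <- function(p_i, p_j) {
  check_proportion(p_i)
  check_proportion(p_j)
  if (any(p_j == 0)) {
    stop("`p_j` must be > 0: the ratio p_i/p_j is undefined at p_j = 0", call. = FALSE)
  }
  tibble::tibble(
    proportion_ratio = p_i / p_j,
    odds_ratio = competitive_index(p_i) / competitive_index(p_j)
  )
}

#' Attach all three fitness estimators to an observation table
#'
#' Computes `p`, `ci`, and `log_ci` from the stored counts for every plate.
#' `p` is always derived from counts (never stored independently) so the
#' `n_gfp <= n_total` invariant stays enforceable. Plates with `n_total = 0`
#' get `NA` for all three estimators; `ci`/`log_ci` carry `NA` at their
#' respective boundaries.
#'
#' @param observations A plate-observation table with integer columns
#'   `n_total` and `n_gfp` (see [read_observations()] for the full schema).
#' @param log_base Base for `log_ci`; natural log by default.
#' @return The input tibble with columns `p`, `ci`, `log_ci` appended.
#' @export
fitness_estimates <- function(observations, log_base = exp(1)) {
  stopifnot(all(c("n_total", "n_gfp") %in% names(observations)))
  check_counts(observations$n_total, observations$n_gfp)
  n_total <- observations$n_total
  n_gfp <- observations$n_gfp
  p <- ifelse(n_total > 0, (n_total - n_gfp) / n_total, NA_real_)
  observations$p <- p
  observations$ci <- ifelse(is.na(p) | p == 1, NA_real_, p / (1 - p))
  observations$log_ci <- ifelse(!is.na(p) & p > 0 & p < 1,
                                log(p / (1 - p), base = log_base), NA_real_)
  tibble::as_tibble(observations)
}
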