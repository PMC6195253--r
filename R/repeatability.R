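#' Re-count repeatability of image-based counting
#'
#' Compares two independent counting passes over the same images (e.g. the
#' same person re-counting a month later, or two software runs). Reports
#' Pearson correlations between passes for the total count, the GFP count,
#' and the focal frequency p, and the mean absolute difference between the
#' two counts expressed as a fraction of their average,
#' `|c1 - c2| / ((c1 + c2)/2)`, as a percentage for total and GFP counts.
#'
#' @param records Tibble with columns `image_id`, `n_total_1`, `n_gfp_1`,
#'   `n_total_2`, `n_gfp_2`; at least 3 usable records. Records with zero
#'   total in both passes are excluded and reported.
#' @return A list: `correlation_total`, `correlation_gfp`, `correlation_p`
#'   (in percent), `mean_abs_rel_diff_total_pct`, `mean_abs_rel_diff_gfp_pct`,
#'   `n_used`, `n_excluded`.
#' @export
recount_analysis <- function(records) {
  needed <- c("n_total_1", "n_gfp_1", "n_total_2", "n_gfp_2")
  stopifnot(all(needed %in% names(records)))
  check_counts(records$n_total_1, records$n_gfp_1)
  check_counts(records$n_total_2, records$n_gfp_2)
  usable <- records$n_total_1 > 0 | records$n_total_2 > 0
  n_excluded <- sum(!usable)
  rec <- records[usable, , drop = FALSE]
  if (nrow(rec) < 3) stop("recount analysis needs >= 3 usable records", call. = FALSE)
  p1 <- rec$n_total_1
  p2 <- rec$n_total_2
  g1 <- rec$n_gfp_1
  g2 <- rec$n_gfp_2
  rel <- function(a, b) {
    avg <- (a + b) / 2
    d <- abs(a - b) / avg
    d[avg == 0] <- 0  # both-zero GFP counts agree exactly
    100 * mean(d)
  }
  prop1 <- (p1 - g1) / p1
  prop2 <- (p2 - g2) / p2
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && all(a == b)) return(100)
    100 * stats::cor(a, b)
  }
  list(
    correlation_total = safe_cor(p1, p2),
    correlation_gfp = safe_cor(g1, g2),
    correlation_p = safe_cor(prop1, prop2),
    mean_abs_rel_diff_total_pct = rel(p1, p2),
    mean_abs_rel_diff_gfp_pct = rel(g1, g2),
    n_used = nrow(rec),
    n_excluded = n_excluded
  )
}

#' Filter split-sample sorter records
#'
#' Worm-sorter samples are ephemeral, so repeatability is assessed by
#' splitting one well into a ~1/4 and a ~3/4 aliquot counted separately.
#' A record is kept only when BOTH aliquots have more than `min_n` worms and
#' a focal frequency strictly inside `(p_lo, p_hi)` — the strict inequalities
#' are deliberate (a 10-worm aliquot is dropped).
#'
#' @param records Tibble with columns `well_id`, `n_total_small`,
#'   `n_gfp_small`, `n_total_large`, `n_gfp_large`.
#' @param min_n Minimum worm count per aliquot (strict `>`); default 10.
#' @param p_lo,p_hi Open interval for the per-aliquot focal frequency;
#'   defaults 0.01 and 0.99.
#' @return A list with `kept` (filtered tibble) and `report` (tibble of
#'   kept/dropped totals and per-criterion drop reasons; a record can fail
#'   several criteria at once).
#' @export
split_sample_filter <- function(records, min_n = 10, p_lo = 0.01, p_hi = 0.99) {
  needed <- c("n_total_small", "n_gfp_small", "n_total_large", "n_gfp_large")
  stopifnot(all(needed %in% names(records)))
  check_counts(records$n_total_small, records$n_gfp_small)
  check_counts(records$n_total_large, records$n_gfp_large)
  p_small <- ifelse(records$n_total_small > 0,
                    (records$n_total_small - records$n_gfp_small) / records$n_total_small, NA_real_)
  p_large <- ifelse(records$n_total_large > 0,
                    (records$n_total_large - records$n_gfp_large) / records$n_total_large, NA_real_)
  fail_n <- records$n_total_small <= min_n | records$n_total_large <= min_n
  fail_p <- is.na(p_small) | is.na(p_large) |
    p_small <= p_lo | p_small >= p_hi | p_large <= p_lo | p_large >= p_hi
  keep <- !fail_n & !fail_p
  report <- tibble::tibble(
    n_input = nrow(records),
    n_kept = sum(keep),
    n_dropped = sum(!keep),
    n_fail_min_n = sum(fail_n),
    n_fail_p_range = sum(fail_p),
    min_n = min_n, p_lo = p_lo, p_hi = p_hi
  )
  list(kept = tibble::as_tibble(records[keep, , drop = FALSE]), report = report)
}

#' Split-sample repeatability analysis
#'
#' For filtered split records (see [split_sample_filter()]) this reports the
#' mean absolute difference in the focal frequency between the two aliquots —
#' headline figure in percentage points of p, with the relative version also
#' given — the Pearson correlation of p between aliquots (percent),
#' per-aliquot means and standard errors of p and of log(CI)
#' (boundary-undefined logs excluded and counted), and the SE ratio expected
#' from the mean aliquot sizes.
#'
#' @param kept Filtered split-sample tibble; at least 3 records.
#' @return A list of summary statistics; see Details in the source.
#' @export
split_sample_analysis <- function(kept) {
  if (nrow(kept) < 3) stop("split-sample analysis needs >= 3 records", call. = FALSE)
  p_small <- focal_frequency(kept$n_total_small, kept$n_gfp_small)
  p_large <- focal_frequency(kept$n_total_large, kept$n_gfp_large)
  logci_small <- log_competitive_index(p_small)
  logci_large <- log_competitive_index(p_large)
  se_mean <- function(x) stats::sd(x) / sqrt(length(x))
  mstats <- function(x) {
    x <- x[!is.na(x)]
    list(mean = mean(x), se = se_mean(x), n = length(x))
  }
  mean_n_small <- mean(kept$n_total_small)
  mean_n_large <- mean(kept$n_total_large)
  list(
    n_wells = nrow(kept),
    mean_abs_diff_p_pct_points = 100 * mean(abs(p_small - p_large)),
    mean_abs_rel_diff_p_pct = 100 * mean(abs(p_small - p_large) / ((p_small + p_large) / 2)),
    correlation_p = 100 * stats::cor(p_small, p_large),
    p_small = mstats(p_small),
    p_large = mstats(p_large),
    logci_small = mstats(logci_small),
    logci_large = mstats(logci_large),
    n_boundary_logci = sum(is.na(logci_small)) + sum(is.na(logci_large)),
    mean_n_small = mean_n_small,
    mean_n_large = mean_n_large,
    expected_se_ratio = se_ratio(mean_n_small, mean_n_large)
  )
}
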