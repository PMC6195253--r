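#' Configuration for the competition-assay simulator
#'
#' Defaults emulate the study design the package is built around: 5 blocks of
#' 24 replicate competitions for every combination of 3 focal strains,
#' 2 GFP-marked competitor strains, and 3 counting methods, with a few
#' hundred worms counted per sample. Biological variation is placed on the
#' log-CI (logit) scale, where variance is least coupled to the mean.
#'
#' @param n_blocks Number of assay blocks (independent temporal replicates).
#' @param focal_strains,competitor_strains,methods Factor level labels.
#' @param reps_per_cell Replicate competitions per
#'   focal x competitor x method cell within a block.
#' @param mu_logci True mean log competitive index. Either a scalar applied
#'   to every focal x competitor cell, or a matrix with focal strains as rows
#'   and competitor strains as columns. Default 0 (neutral competition).
#' @param sigma_block SD of block effects on the log-CI scale.
#' @param sigma_bio SD of among-plate biological deviations on the log-CI
#'   scale (beyond block effects).
#' @param worms_per_sample Mean worms counted per sample; plate totals are
#'   Poisson with this mean unless `worms_dispersion` is finite, in which
#'   case they are negative binomial with that `size`.
#' @param worms_dispersion Negative-binomial size parameter (Inf = Poisson).
#' @param method_error Named list (one entry per method) of lists with
#'   `fp_worm_rate` (expected extra non-worm objects per true worm),
#'   `fn_gfp_rate` (probability a GFP worm is read as non-GFP), and
#'   `miscount_sd` (relative SD of total-count noise). The defaults are
#'   order-of-magnitude guesses — no empirical per-method error rates are
#'   available — and should be treated as illustrative, not estimated.
#' @param split_fraction Volumetric fraction of the small aliquot when
#'   splitting a well (default 1/4).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_blocks = 5,
                              focal_strains = c("N2", "PB306", "CB4856"),
                              competitor_strains = c("ST2", "VP604"),
                              methods = c("by_eye", "cellprofiler", "sorter"),
                              reps_per_cell = 24,
                              mu_logci = 0,
                              sigma_block = 0.25,
                              sigma_bio = 1.0,
                              worms_per_sample = 176,
                              worms_dispersion = Inf,
                              method_error = default_method_error(methods),
                              split_fraction = 0.25,
                              seed = 1L) {
  if (sigma_block < 0 || sigma_bio < 0) stop("sigmas must be >= 0", call. = FALSE)
  if (reps_per_cell < 1) stop("`reps_per_cell` must be >= 1", call. = FALSE)
  if (worms_per_sample <= 0) stop("`worms_per_sample` must be positive", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("`split_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (is.matrix(mu_logci)) {
    if (!identical(dim(mu_logci), c(length(focal_strains), length(competitor_strains)))) {
      stop("`mu_logci` matrix must be focal x competitor", call. = FALSE)
    }
  } else if (length(mu_logci) != 1L) {
    stop("`mu_logci` must be a scalar or a focal x competitor matrix", call. = FALSE)
  }
  if (!all(methods %in% names(method_error))) {
    stop("`method_error` must have one entry per method", call. = FALSE)
  }
  for (me in method_error) {
    if (me$fp_worm_rate < 0 || me$fn_gfp_rate < 0 || me$fn_gfp_rate > 1 || me$miscount_sd < 0) {
      stop("method error rates out of range", call. = FALSE)
    }
  }
  structure(list(
    n_blocks = n_blocks, focal_strains = focal_strains,
    competitor_strains = competitor_strains, methods = methods,
    reps_per_cell = reps_per_cell, mu_logci = mu_logci,
    sigma_block = sigma_block, sigma_bio = sigma_bio,
    worms_per_sample = worms_per_sample, worms_dispersion = worms_dispersion,
    method_error = method_error, split_fraction = split_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default per-method counting-error parameters
#'
#' Order-of-magnitude guesses, labelled as such: image analysis is modestly
#' prone to both false-positive worm objects (debris called worms) and
#' false-negative GFP calls (fluorescent locus missed, e.g. in a truncated
#' head region), both of which inflate the focal frequency; manual counting
#' errs rarely; the sorter has some false-positive small events.
#'
#' @param methods Method labels.
#' @return Named list of error-parameter lists.
#' @export
default_method_error <- function(methods = c("by_eye", "cellprofiler", "sorter")) {
  base <- list(
    by_eye = list(fp_worm_rate = 0.002, fn_gfp_rate = 0.002, miscount_sd = 0.005),
    cellprofiler = list(fp_worm_rate = 0.02, fn_gfp_rate = 0.02, miscount_sd = 0.01),
    sorter = list(fp_worm_rate = 0.01, fn_gfp_rate = 0.005, miscount_sd = 0.01)
  )
  out <- lapply(methods, function(m) {
    if (m %in% names(base)) base[[m]] else list(fp_worm_rate = 0.01, fn_gfp_rate = 0.01, miscount_sd = 0.01)
  })
  names(out) <- methods
  out
}

#' Preset: assay-like scenario with distinct strain fitnesses
#'
#' The neutral default (`mu_logci = 0`) is useful for null calibrations, but
#' a realistic head-to-head assay involves focal strains of genuinely
#' different competitive ability against two marker strains. This preset
#' keeps the default design (5 blocks x 3 focal x 2 competitor x 3 methods
#' x 24 replicates) and sets a mean log-CI matrix spanning strong to weak
#' focal performance on the focal-favoured side (group-level p from roughly
#' 0.51 to 0.80, overall mean near 0.6, as in assays where wild-type focal
#' strains outcompete GFP-marked references), which is what gives the
#' mean-variance diagnostics something real to measure.
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
paper_like_config <- function(seed = 1L, ...) {
  mu <- matrix(c(1.4, 1.0,
                 0.7, 0.45,
                 0.25, 0.05),
               nrow = 3, byrow = TRUE,
               dimnames = list(c("N2", "PB306", "CB4856"), c("ST2", "VP604")))
  simulation_config(mu_logci = mu, seed = seed, ...)
}

cell_mu <- function(config, focal, competitor) {
  if (is.matrix(config$mu_logci)) {
    fi <- match(focal, config$focal_strains)
    cj <- match(competitor, config$competitor_strains)
    config$mu_logci[cbind(fi, cj)]
  } else {
    rep(config$mu_logci, length(focal))
  }
}

#' Simulate a full competition assay
#'
#' Per plate: the true log competitive index is
#' `mu_logci[cell] + block_effect + N(0, sigma_bio)`; the true focal
#' frequency is its inverse logit; the realized total count is Poisson (or
#' negative binomial); focal worms are a binomial draw at the true p; and the
#' observed counts pass through [apply_method_error()] with the plate's
#' method-specific error parameters. Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list: `observations` (plate-observation tibble with columns
#'   `block_id`, `focal_strain`, `competitor_strain`, `method`,
#'   `replicate_id`, `n_total`, `n_gfp`) and `truth` (per-plate true p,
#'   true log CI, block effects, and pre-error counts).
#' @export
simulate_assay <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_assay_impl(config))
}

simulate_assay_impl <- function(config) {
  grid <- expand.grid(
    replicate_id = seq_len(config$reps_per_cell),
    method = config$methods,
    competitor_strain = config$competitor_strains,
    focal_strain = config$focal_strains,
    block_id = paste0("block", seq_len(config$n_blocks)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  block_effects <- stats::rnorm(config$n_blocks, 0, config$sigma_block)
  names(block_effects) <- paste0("block", seq_len(config$n_blocks))
  logci_true <- cell_mu(config, grid$focal_strain, grid$competitor_strain) +
    block_effects[grid$block_id] +
    stats::rnorm(n, 0, config$sigma_bio)
  p_true <- stats::plogis(logci_true)
  n_total_true <- if (is.finite(config$worms_dispersion)) {
    stats::rnbinom(n, size = config$worms_dispersion, mu = config$worms_per_sample)
  } else {
    stats::rpois(n, config$worms_per_sample)
  }
  n_focal_true <- stats::rbinom(n, n_total_true, p_true)
  n_gfp_true <- n_total_true - n_focal_true
  obs <- matrix(0L, n, 2L)
  for (m in config$methods) {
    idx <- grid$method == m
    obs[idx, ] <- apply_method_error(n_total_true[idx], n_gfp_true[idx],
                                     config$method_error[[m]])
  }
  observations <- tibble::tibble(
    block_id = grid$block_id,
    focal_strain = grid$focal_strain,
    competitor_strain = grid$competitor_strain,
    method = grid$method,
    replicate_id = paste0("rep", grid$replicate_id),
    n_total = obs[, 1L],
    n_gfp = obs[, 2L]
  )
  truth <- tibble::tibble(
    observations[, c("block_id", "focal_strain", "competitor_strain", "method", "replicate_id")],
    logci_true = logci_true,
    p_true = p_true,
    block_effect = unname(block_effects[grid$block_id]),
    n_total_true = n_total_true,
    n_gfp_true = n_gfp_true
  )
  list(observations = observations, truth = truth)
}

#' Apply method-specific counting error to true plate counts
#'
#' GFP worms are missed independently with probability `fn_gfp_rate`
#' (binomial thinning of the GFP count); false-positive objects are added to
#' the total as a Poisson draw with mean `fp_worm_rate * n_total_true`; and a
#' rounded Gaussian miscount with SD `miscount_sd * n_total_true` perturbs
#' the total. The observed total is floored at the observed GFP count so the
#' count invariant always holds. Uses the current RNG stream.
#'
#' @param n_total_true,n_gfp_true Integer vectors of true counts.
#' @param error A list with `fp_worm_rate`, `fn_gfp_rate`, `miscount_sd`.
#' @return Integer matrix with columns (n_total, n_gfp).
#' @export
apply_method_error <- function(n_total_true, n_gfp_true, error) {
  check_counts(n_total_true, n_gfp_true)
  n <- length(n_total_true)
  n_gfp_obs <- stats::rbinom(n, n_gfp_true, 1 - error$fn_gfp_rate)
  fp <- stats::rpois(n, error$fp_worm_rate * n_total_true)
  noise <- round(stats::rnorm(n, 0, error$miscount_sd * n_total_true))
  n_total_obs <- pmax(n_gfp_obs, n_total_true + fp + as.integer(noise))
  cbind(n_total = as.integer(n_total_obs), n_gfp = as.integer(n_gfp_obs))
}

#' Simulate sorter split samples
#'
#' Each well's worm population is split volumetrically into a small and a
#' large aliquot: the small-aliquot size is Binomial(n, split_fraction)
#' (volumetric split of a well-mixed suspension), and its GFP composition is
#' the corresponding hypergeometric draw. Both aliquots are recorded.
#'
#' @param config A [simulation_config()]; uses `split_fraction`, `mu_logci`
#'   (scalar or first cell), `sigma_bio`, and `seed`.
#' @param n_wells Number of wells to split.
#' @param worms_per_well Mean total worms per well before splitting. The
#'   default 694 puts the aliquot sizes in the ~170/~520 regime of a
#'   quarter/three-quarter split of a typical sorter well.
#' @return A list: `records` (tibble with `well_id`, `n_total_small`,
#'   `n_gfp_small`, `n_total_large`, `n_gfp_large`) and `truth` (per-well
#'   true p and counts).
#' @export
simulate_split_samples <- function(config = simulation_config(), n_wells = 336,
                                   worms_per_well = 694) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    mu <- if (is.matrix(config$mu_logci)) config$mu_logci[1L] else config$mu_logci
    logci_true <- mu + stats::rnorm(n_wells, 0, config$sigma_bio)
    p_true <- stats::plogis(logci_true)
    n_total <- stats::rpois(n_wells, worms_per_well)
    n_gfp <- n_total - stats::rbinom(n_wells, n_total, p_true)
    n_small <- stats::rbinom(n_wells, n_total, config$split_fraction)
    # hypergeometric composition: which of the GFP worms land in the small aliquot
    n_gfp_small <- stats::rhyper(n_wells, m = n_gfp, n = n_total - n_gfp, k = n_small)
    records <- tibble::tibble(
      well_id = paste0("well", seq_len(n_wells)),
      n_total_small = n_small,
      n_gfp_small = n_gfp_small,
      n_total_large = n_total - n_small,
      n_gfp_large = n_gfp - n_gfp_small
    )
    truth <- tibble::tibble(
      well_id = records$well_id,
      logci_true = logci_true, p_true = p_true,
      n_total = n_total, n_gfp = n_gfp
    )
    list(records = records, truth = truth)
  })
}
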