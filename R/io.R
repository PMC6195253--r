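#' Read a plate-observation table
#'
#' The canonical format is a UTF-8 CSV with header columns `block_id`,
#' `focal_strain`, `competitor_strain`, `method`, `replicate_id`, `n_total`,
#' `n_gfp`. Spreadsheets shaped like raw-data supplementary tables can be
#' ingested via `format = "xlsx"` together with a column `mapping`. Rows
#' violating `0 <= n_gfp <= n_total` are rejected with their line numbers
#' (reported in a warning and in the `rejected` attribute); missing columns
#' or unparseable numerics are an error listing the offenders.
#'
#' @param path File path.
#' @param format `"csv"` (canonical) or `"xlsx"` (read-only convenience;
#'   requires the readxl package).
#' @param mapping Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(n_total = "Total Worms", n_gfp = "GFP Worms")`.
#' @param sheet Sheet index or name for xlsx input.
#' @return A validated tibble in the canonical schema; rejected row numbers
#'   in `attr(, "rejected")`.
#' @export
read_observations <- function(path, format = c("csv", "xlsx"), mapping = NULL,
                              sheet = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("xlsx ingestion requires the readxl package", call. = FALSE)
    }
    readxl::read_excel(path, sheet = sheet)
  }
  canonical <- c("block_id", "focal_strain", "competitor_strain", "method",
                 "replicate_id", "n_total", "n_gfp")
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      if (!mapping[[canon]] %in% names(raw)) {
        stop("mapped column not found in file: ", mapping[[canon]], call. = FALSE)
      }
      names(raw)[names(raw) == mapping[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(canonical, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  obs <- tibble::as_tibble(raw[canonical])
  for (col in c("n_total", "n_gfp")) {
    v <- suppressWarnings(as.numeric(obs[[col]]))
    bad <- which(is.na(v) & !is.na(obs[[col]]))
    if (length(bad)) {
      stop("unparseable numeric in `", col, "` at data row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    obs[[col]] <- as.integer(round(v))
  }
  bad_rows <- which(is.na(obs$n_total) | is.na(obs$n_gfp) |
                      obs$n_total < 0 | obs$n_gfp < 0 | obs$n_gfp > obs$n_total)
  if (length(bad_rows)) {
    warning("rejected ", length(bad_rows),
            " row(s) violating 0 <= n_gfp <= n_total; data row number(s): ",
            paste(utils::head(bad_rows, 20L), collapse = ", "))
    obs <- obs[-bad_rows, , drop = FALSE]
  }
  for (col in c("block_id", "focal_strain", "competitor_strain", "method", "replicate_id")) {
    obs[[col]] <- as.character(obs[[col]])
  }
  attr(obs, "rejected") <- bad_rows
  obs
}

#' Write a plate-observation table to the canonical CSV
#'
#' @param observations Tibble in the canonical schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  canonical <- c("block_id", "focal_strain", "competitor_strain", "method",
                 "replicate_id", "n_total", "n_gfp")
  stopifnot(all(canonical %in% names(observations)))
  readr::write_csv(observations[canonical], path, progress = FALSE)
  invisible(path)
}

#' Run the full method-comparison pipeline
#'
#' Simulates (or loads) a plate-observation table, then runs the complete
#' analysis chain: fitness estimators, within-block variability summaries
#' with mean-variance diagnostics, split-sample repeatability, and both
#' model-based method comparisons (SD of log(CI), and p with a block random
#' intercept). Writes CSV/JSON reports plus a MANIFEST with the seed,
#' package version, and completion status of every stage; a stage failure
#' aborts with the failing stage named, with earlier outputs retained and
#' the MANIFEST marking incompleteness.
#'
#' @param out_dir Output directory (created if needed).
#' @param observations Optional plate-observation tibble; when `NULL` one is
#'   simulated from `sim_config`.
#' @param sim_config A [simulation_config()] used when simulating and for
#'   the split-sample stage.
#' @param n_split_wells Wells for the split-sample stage (0 skips it).
#' @param seed Integer seed recorded in the MANIFEST and used to derive the
#'   simulation config seed when one is simulated.
#' @param plots Also write mean-variance scatter plots (requires ggplot2).
#' @return A list with every stage's results (invisibly also written under
#'   `out_dir`).
#' @export
run_pipeline <- function(out_dir, observations = NULL,
                         sim_config = simulation_config(seed = seed),
                         n_split_wells = 336, seed = 1L, plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("compfit")),
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list(), complete = FALSE)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest()
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 2))
    write_manifest()
    res
  }
  results <- list()
  results$observations <- stage("observations", {
    obs <- if (is.null(observations)) simulate_assay(sim_config)$observations else observations
    if (nrow(obs) == 0) stop("empty observation table")
    write_observations(obs, file.path(out_dir, "observations.csv"))
    obs
  })
  obs <- results$observations
  results$estimates <- stage("estimates", {
    est <- fitness_estimates(obs)
    readr::write_csv(est, file.path(out_dir, "fitness_estimates.csv"), progress = FALSE)
    est
  })
  results$diagnostics <- stage("variability", {
    diag <- mean_variance_diagnostics(obs)
    readr::write_csv(diag$correlations, file.path(out_dir, "mean_variance_correlations.csv"), progress = FALSE)
    readr::write_csv(diag$scatter, file.path(out_dir, "mean_variance_scatter.csv"), progress = FALSE)
    diag
  })
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    stage("plots", {
      sc <- results$diagnostics$scatter
      gg <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$mean, y = .data$variability)) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::facet_grid(metric ~ variability_measure, scales = "free") +
        ggplot2::labs(x = "group mean", y = "group variability")
      ggplot2::ggsave(file.path(out_dir, "mean_variance.png"), gg,
                      width = 6, height = 7, dpi = 150)
      TRUE
    })
  }
  if (n_split_wells > 0) {
    results$split <- stage("split_samples", {
      splits <- simulate_split_samples(sim_config, n_wells = n_split_wells)
      filt <- split_sample_filter(splits$records)
      ana <- split_sample_analysis(filt$kept)
      readr::write_csv(splits$records, file.path(out_dir, "split_samples.csv"), progress = FALSE)
      jsonlite::write_json(list(filter = filt$report, analysis = ana),
                           file.path(out_dir, "split_sample_report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      list(records = splits$records, filter = filt, analysis = ana)
    })
  }
  results$sd_logci <- stage("model_sd_logci", {
    ana <- analyze_sd_logci(obs)
    jsonlite::write_json(model_report(ana), file.path(out_dir, "model_sd_logci.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ana
  })
  results$p_model <- stage("model_p", {
    ana <- analyze_p(obs)
    jsonlite::write_json(model_report(ana), file.path(out_dir, "model_p.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ana
  })
  manifest$complete <- TRUE
  manifest$finished <- format(Sys.time(), tz = "UTC")
  write_manifest()
  invisible(results)
}

# JSON-serializable view of an analyze_* result
model_report <- function(ana) {
  fit <- ana$fit
  list(
    best_spec = list(response = fit$spec$response, fixed = fit$spec$fixed,
                     random = fit$spec$random, resid_group = fit$spec$resid_group),
    criterion = fit$criterion,
    coefficients = as.list(fit$beta),
    residual_variances = as.list(fit$sigma2),
    block_variance = fit$sigma2_block,
    logLik = fit$logLik, k = fit$k, n = fit$n, aicc = fit$aicc,
    search_variance = ana$search_variance,
    search_fixed = ana$search_fixed,
    f_test_method = as.list(ana$f_test_method[1, ])
  )
}
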