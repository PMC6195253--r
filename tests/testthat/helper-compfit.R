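# shared fixtures, built in code

no_error <- function(methods = c("by_eye", "cellprofiler", "sorter")) {
  out <- lapply(methods, function(m) list(fp_worm_rate = 0, fn_gfp_rate = 0, miscount_sd = 0))
  names(out) <- methods
  out
}

small_assay_config <- function(seed = 1L, ...) {
  simulation_config(n_blocks = 3, reps_per_cell = 6, seed = seed, ...)
}

# a tiny observation table with known counts
toy_observations <- function() {
  tibble::tibble(
    block_id = rep("b1", 6),
    focal_strain = rep(c("N2", "PB306"), each = 3),
    competitor_strain = "ST2",
    method = "by_eye",
    replicate_id = paste0("r", 1:6),
    n_total = c(100L, 100L, 100L, 200L, 200L, 200L),
    n_gfp = c(60L, 50L, 40L, 100L, 90L, 110L)
  )
}

# hand-built image pair: horizontal bar worms on a flat bright background
bar_pair <- function(nr = 120, nc = 120, bars = list(), gfp_at = list(),
                     bg = 0.9, dark = 0.2, fluo_bg = 0.05, fluo_peak = 0.95) {
  bf <- matrix(bg, nr, nc)
  for (b in bars) bf[b$rows, b$cols] <- dark
  fl <- matrix(fluo_bg, nr, nc)
  for (g in gfp_at) {
    rr <- (g$row - 2):(g$row + 2)
    cc <- (g$col - 2):(g$col + 2)
    rr <- rr[rr >= 1 & rr <= nr]; cc <- cc[cc >= 1 & cc <= nc]
    fl[rr, cc] <- fluo_peak
  }
  structure(list(brightfield = bf, fluorescence = fl,
                 truth = tibble::tibble(), config = NULL),
            class = "well_image_pair")
}
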