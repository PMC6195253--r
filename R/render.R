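#' Rendering configuration for synthetic well images
#'
#' Controls the geometry and photometry of rendered brightfield/fluorescence
#' well-image pairs. Worms are drawn as smooth random-curvature tubes lying
#' inside a circular well; the brightfield channel shows dark worms on a
#' bright background modulated by a radial illumination field in which the
#' well centre is bright and the edges dark; the fluorescence channel shows a
#' compact bright locus inside each GFP worm. Defaults include mild clumping
#' and mild (small, sub-worm-sized) debris.
#'
#' @param width,height Image size in pixels.
#' @param well_radius_frac Well radius as a fraction of the smaller image
#'   dimension.
#' @param worm_length Centerline length in pixels.
#' @param worm_width Tube width in pixels.
#' @param curvature_sd SD of the per-step heading increment (radians).
#' @param bg_level,worm_level Background and worm brightfield intensities
#'   before illumination modulation.
#' @param illum_center,illum_edge Radial illumination multipliers at the
#'   image centre and at the well edge.
#' @param noise_sd Additive Gaussian pixel noise SD (both channels).
#' @param clump_prob Probability that a worm is placed touching an existing
#'   worm (0 disables clumping and enforces strict separation).
#' @param debris_rate Expected number of debris specks per image (Poisson).
#' @param debris_area Speck area in pixels; the default is below typical
#'   minimum-object-area filters (mild debris); raise it to create
#'   worm-sized false positives.
#' @param debris_edge_bias Fraction of the well radius below which debris is
#'   never placed (debris concentrates toward the well edge).
#' @param gfp_head_frac Position of the GFP locus along the centerline,
#'   as a fraction from the head.
#' @param gfp_peak,gfp_sigma,fluo_bg Fluorescent spot peak intensity,
#'   Gaussian radius (pixels), and fluorescence background level.
#' @return A list of class `render_config`.
#' @export
render_config <- function(width = 256, height = 256, well_radius_frac = 0.47,
                          worm_length = 48, worm_width = 5, curvature_sd = 0.15,
                          bg_level = 0.85, worm_level = 0.35,
                          illum_center = 1.0, illum_edge = 0.55,
                          noise_sd = 0.015, clump_prob = 0.15,
                          debris_rate = 8, debris_area = 6,
                          debris_edge_bias = 0.6,
                          gfp_head_frac = 0.15, gfp_peak = 0.9,
                          gfp_sigma = 1.8, fluo_bg = 0.05) {
  structure(as.list(environment()), class = "render_config")
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

stamp <- function(mask, rows, cols, offs) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- rep(rows, each = nrow(offs)) + offs$dr
  cc <- rep(cols, each = nrow(offs)) + offs$dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  mask[cbind(rr[ok], cc[ok])] <- TRUE
  mask
}

# one random-curvature centerline confined to the well interior
draw_centerline <- function(cfg, cx, cy, well_r, start = NULL) {
  margin <- cfg$worm_width
  len <- cfg$worm_length
  if (is.null(start)) {
    repeat {
      a <- stats::runif(1, 0, 2 * pi)
      r <- sqrt(stats::runif(1)) * (well_r - margin - len / 3)
      start <- c(cy + r * sin(a), cx + r * cos(a))
      break
    }
  }
  heading <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, len, 2L)
  pos <- start
  for (i in seq_len(len)) {
    pts[i, ] <- pos
    heading <- heading + stats::rnorm(1, 0, cfg$curvature_sd)
    nxt <- pos + c(sin(heading), cos(heading))
    # steer back toward the well centre when approaching the edge
    if (sqrt((nxt[1] - cy)^2 + (nxt[2] - cx)^2) > well_r - margin) {
      heading <- atan2(cy - pos[1], cx - pos[2]) + stats::rnorm(1, 0, 0.3)
      nxt <- pos + c(sin(heading), cos(heading))
    }
    pos <- nxt
  }
  pts
}

#' Render a synthetic brightfield/fluorescence well-image pair
#'
#' Draws `n_worms` random-curvature tube worms inside a circular well, marks
#' a `gfp_fraction` share of them with a fluorescent locus, applies the
#' radial illumination field (bright centre, dark edges), adds noise and
#' optional debris, and embeds the per-worm ground truth.
#'
#' @param n_worms Number of worms to draw (>= 0).
#' @param gfp_fraction Fraction of worms that carry the GFP marker; the
#'   realized count is `round(n_worms * gfp_fraction)`.
#' @param config A [render_config()].
#' @param seed Optional integer; when given the rendering is a pure function
#'   of (arguments, seed), otherwise the current RNG stream is used.
#' @return A list of class `well_image_pair`: `brightfield` and
#'   `fluorescence` matrices (rows = y), `truth` tibble (`worm_id`,
#'   `is_gfp`, `row`, `col` centroid, `centerline` list-column,
#'   `gfp_row`/`gfp_col` locus position), and `config`.
#' @export
render_well_image <- function(n_worms, gfp_fraction = 0.5,
                              config = render_config(), seed = NULL) {
  if (n_worms < 0) stop("`n_worms` must be >= 0", call. = FALSE)
  run <- function() render_well_image_impl(n_worms, gfp_fraction, config)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

render_well_image_impl <- function(n_worms, gfp_fraction, cfg) {
  nr <- cfg$height; nc <- cfg$width
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  well_r <- cfg$well_radius_frac * min(nr, nc)
  tube <- disc_offsets(cfg$worm_width / 2)
  worm_mask <- matrix(FALSE, nr, nc)
  occupied <- matrix(FALSE, nr, nc)   # dilated occupancy for separation checks
  occ_touch <- matrix(FALSE, nr, nc)  # tighter occupancy: clumps may touch, not overlap
  sep <- disc_offsets(cfg$worm_width + 2)
  sep_touch <- disc_offsets(max(1, cfg$worm_width - 1))
  n_gfp <- round(n_worms * gfp_fraction)
  is_gfp <- rep(c(TRUE, FALSE), c(n_gfp, n_worms - n_gfp))
  worms <- vector("list", n_worms)
  for (w in seq_len(n_worms)) {
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      allow_touch <- cfg$clump_prob > 0 && stats::runif(1) < cfg$clump_prob && w > 1L
      start <- NULL
      if (allow_touch) {
        prev <- worms[[sample.int(w - 1L, 1L)]]$centerline
        anchor <- prev[sample.int(nrow(prev), 1L), ]
        a <- stats::runif(1, 0, 2 * pi)
        start <- anchor + cfg$worm_width * c(sin(a), cos(a))
        if (sqrt((start[1] - cy)^2 + (start[2] - cx)^2) > well_r - cfg$worm_width) next
      }
      pts <- draw_centerline(cfg, cx, cy, well_r, start = start)
      ri <- round(pts[, 1L]); ci <- round(pts[, 2L])
      if (!allow_touch && any(occupied[cbind(ri, ci)])) next
      if (allow_touch && any(occ_touch[cbind(ri, ci)])) next
      worm_mask <- stamp(worm_mask, ri, ci, tube)
      occupied <- stamp(occupied, ri, ci, sep)
      occ_touch <- stamp(occ_touch, ri, ci, sep_touch)
      locus_idx <- max(1L, round(cfg$gfp_head_frac * nrow(pts)))
      worms[[w]] <- list(
        worm_id = w, is_gfp = is_gfp[w],
        row = mean(pts[, 1L]), col = mean(pts[, 2L]),
        gfp_row = pts[locus_idx, 1L], gfp_col = pts[locus_idx, 2L],
        centerline = pts
      )
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place worm ", w, " without overlap; the well is at its ",
           "packing limit - render fewer worms or enlarge the image", call. = FALSE)
    }
  }
  # debris specks, biased toward the well edge
  n_debris <- stats::rpois(1, cfg$debris_rate)
  debris_mask <- matrix(FALSE, nr, nc)
  if (n_debris > 0) {
    offs <- disc_offsets(sqrt(cfg$debris_area / pi))
    for (i in seq_len(n_debris)) {
      a <- stats::runif(1, 0, 2 * pi)
      rfrac <- cfg$debris_edge_bias + (1 - cfg$debris_edge_bias) * sqrt(stats::runif(1))
      r <- rfrac * (well_r - 2)
      debris_mask <- stamp(debris_mask, round(cy + r * sin(a)), round(cx + r * cos(a)), offs)
    }
  }
  # brightfield: dark worms and debris on bright background x radial illumination
  bf <- matrix(cfg$bg_level, nr, nc)
  bf[worm_mask | debris_mask] <- cfg$worm_level
  rad2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`) / well_r^2
  illum <- cfg$illum_center - (cfg$illum_center - cfg$illum_edge) * pmin(rad2, 1)
  bf <- bf * illum + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
  bf <- pmin(pmax(bf, 0), 1.5)
  # fluorescence: compact bright locus inside each GFP worm
  fl <- matrix(cfg$fluo_bg, nr, nc)
  spot_r <- ceiling(3 * cfg$gfp_sigma)
  spot_offs <- disc_offsets(spot_r)
  spot_val <- cfg$gfp_peak * exp(-(spot_offs$dr^2 + spot_offs$dc^2) / (2 * cfg$gfp_sigma^2))
  for (w in worms) {
    if (!w$is_gfp) next
    rr <- round(w$gfp_row) + spot_offs$dr
    cc <- round(w$gfp_col) + spot_offs$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    idx <- cbind(rr[ok], cc[ok])
    fl[idx] <- pmax(fl[idx], cfg$fluo_bg + spot_val[ok])
  }
  fl <- fl + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
  fl <- pmin(pmax(fl, 0), 1.5)
  truth <- if (n_worms > 0) {
    tibble::tibble(
      worm_id = vapply(worms, `[[`, numeric(1), "worm_id"),
      is_gfp = vapply(worms, `[[`, logical(1), "is_gfp"),
      row = vapply(worms, `[[`, numeric(1), "row"),
      col = vapply(worms, `[[`, numeric(1), "col"),
      gfp_row = vapply(worms, `[[`, numeric(1), "gfp_row"),
      gfp_col = vapply(worms, `[[`, numeric(1), "gfp_col"),
      centerline = lapply(worms, `[[`, "centerline")
    )
  } else {
    tibble::tibble(worm_id = numeric(), is_gfp = logical(), row = numeric(),
                   col = numeric(), gfp_row = numeric(), gfp_col = numeric(),
                   centerline = list())
  }
  structure(list(brightfield = bf, fluorescence = fl, truth = truth,
                 config = cfg), class = "well_image_pair")
}

#' Ground-truth counts of a rendered pair, honouring a crop
#'
#' Worms whose centroid falls outside the cropped frame are excluded from
#' the truth, matching how a cropped image is evaluated.
#'
#' @param pair A `well_image_pair`.
#' @param crop_fraction Border fraction as in [crop_well()].
#' @return A list with `n_total` and `n_gfp`.
#' @export
truth_counts <- function(pair, crop_fraction = 0) {
  tr <- pair$truth
  if (crop_fraction > 0 && nrow(tr) > 0) {
    d <- dim(pair$brightfield)
    b <- floor(crop_fraction * min(d))
    inside <- tr$row > b & tr$row <= d[1L] - b & tr$col > b & tr$col <= d[2L] - b
    tr <- tr[inside, , drop = FALSE]
  }
  list(n_total = nrow(tr), n_gfp = sum(tr$is_gfp))
}
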