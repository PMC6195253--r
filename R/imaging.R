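#' Correct uneven illumination in a well image
#'
#' Estimates a smooth background by heavy Gaussian smoothing at a
#' configurable scale and divides it out (or subtracts it), rescaling so the
#' mean intensity is preserved. Division is the default because well images
#' typically show a multiplicative radial field (bright centre, dark edges).
#' Rank order within local neighbourhoods is preserved. Smoothing uses a
#' normalized separable Gaussian convolution, so boundaries introduce no
#' darkening artefacts.
#'
#' @param image Numeric matrix of non-negative intensities.
#' @param sigma Gaussian scale in pixels; default 1/16 of the smaller image
#'   dimension - heavy relative to any worm, light enough to track the
#'   radial field near the image border.
#' @param mode `"divide"` (default) or `"subtract"`.
#' @return Corrected matrix of the same size. A constant image is returned
#'   unchanged with a warning.
#' @export
correct_illumination <- function(image, sigma = min(dim(image)) / 16,
                                 mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (stats::sd(image) == 0) {
    warning("constant image: nothing to correct")
    return(image)
  }
  bg <- gauss_smooth(image, sigma)
  if (mode == "divide") {
    image / pmax(bg, 1e-8) * mean(bg)
  } else {
    image - bg + mean(bg)
  }
}

# normalized separable Gaussian smoothing; boundary handled by renormalizing
# against the smoothed all-ones image
gauss_smooth <- function(mat, sigma) {
  k1 <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    K <- exp(-d^2 / (2 * sigma^2))
    K / rowSums(K)
  }
  Kr <- k1(nrow(mat))
  Kc <- k1(ncol(mat))
  Kr %*% mat %*% t(Kc)
}

#' Crop a uniform border from a well image
#'
#' Removes a border of `crop_fraction * min(dim)` pixels from each side.
#' Cropping reduces false positives from edge debris and the poorly
#' illuminated well rim, at the cost of discarding worms near the edge.
#'
#' @param image Numeric matrix.
#' @param crop_fraction Border fraction in `[0, 0.5)`; 0 is the identity.
#' @return The cropped matrix.
#' @export
crop_well <- function(image, crop_fraction) {
  stopifnot(is.matrix(image))
  if (crop_fraction < 0 || crop_fraction >= 0.5) {
    stop("`crop_fraction` must be in [0, 0.5)", call. = FALSE)
  }
  if (crop_fraction == 0) return(image)
  b <- floor(crop_fraction * min(dim(image)))
  if (nrow(image) - 2 * b < 2 || ncol(image) - 2 * b < 2) {
    stop("crop too large for this image", call. = FALSE)
  }
  image[(b + 1):(nrow(image) - b), (b + 1):(ncol(image) - b), drop = FALSE]
}

#' Segmentation parameters for the worm counter
#'
#' @param min_area Smallest component (pixels) kept as a putative worm;
#'   smaller specks are treated as debris.
#' @param single_area_mult Components up to this multiple of the reference
#'   worm area are counted as one worm; larger ones are clumps.
#' @param max_area_mult Components above this multiple of the reference
#'   area are discarded (well rim, large artefacts).
#' @param reference_worm_area Fallback single-worm area in pixels, used when
#'   an image contains no single-worm-sized component to estimate it from;
#'   otherwise the reference is the median area of multiplicity-1 components
#'   of the image itself.
#' @param estimate_reference Estimate the reference area per image (default);
#'   set `FALSE` to force `reference_worm_area`, e.g. for sparse images
#'   where most objects are clumps and the median is not a single worm.
#' @param min_gfp_area Smallest fluorescent component treated as a GFP
#'   object.
#' @param min_contrast Minimum relative intensity depression (dark objects
#'   vs background) for the brightfield threshold to engage; an image with
#'   less contrast than this is treated as worm-free rather than letting a
#'   global threshold slice its noise floor.
#' @return A list of class `seg_params`.
#' @export
segmentation_params <- function(min_area = 20, single_area_mult = 1.6,
                                max_area_mult = 20, reference_worm_area = 200,
                                estimate_reference = TRUE, min_gfp_area = 4,
                                min_contrast = 0.1) {
  structure(as.list(environment()), class = "seg_params")
}

# centroids (row, col) of the listed component ids in a label matrix
component_centroids <- function(lab, ids) {
  K <- length(ids)
  idx <- which(lab > 0)
  pos <- match(as.integer(lab[idx]), ids)
  ok <- !is.na(pos)
  idx <- idx[ok]
  pos <- pos[ok]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  sr <- rowsum(rows, pos)
  sc <- rowsum(cols, pos)
  cnt <- rowsum(rep(1L, length(pos)), pos)
  o <- as.integer(rownames(sr))
  out_r <- rep(NA_real_, K); out_c <- rep(NA_real_, K)
  out_r[o] <- sr[, 1L] / cnt[, 1L]
  out_c[o] <- sc[, 1L] / cnt[, 1L]
  list(row = out_r, col = out_c)
}

norm01 <- function(x) {
  r <- range(x)
  if (r[1L] == r[2L]) return(matrix(0, nrow(x), ncol(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Segment putative worm objects from a brightfield image
#'
#' Worms are dark on a bright background, so the (illumination-corrected)
#' image is inverted and normalized, thresholded globally by Otsu's method,
#' and labelled into connected components. Components below `min_area` or
#' above `max_area_mult` times the reference worm area are discarded.
#' Components larger than `single_area_mult` times the reference area are
#' treated as clumps of touching worms and assigned a multiplicity of
#' `round(area / reference_area)` — an area-quantization stand-in for
#' model-based worm untangling. The reference area is estimated per image
#' as the median area of single-worm-sized components.
#'
#' @param brightfield Illumination-corrected brightfield matrix.
#' @param params A [segmentation_params()].
#' @return A list: `labels` (integer matrix; 0 = background, discarded
#'   components zeroed), `objects` tibble (`id`, `area`, `multiplicity`,
#'   `row`, `col` centroid), `reference_area`, `threshold`. An image with no
#'   foreground yields zero objects, not an error.
#' @export
segment_worms <- function(brightfield, params = segmentation_params()) {
  stopifnot(is.matrix(brightfield))
  # minimum-contrast guard: dark objects must depress intensity well below
  # the background level, otherwise Otsu would slice the noise floor of a
  # worm-free image into spurious foreground; measured over the central
  # region, where illumination correction is most reliable
  nr <- nrow(brightfield); nc <- ncol(brightfield)
  central <- outer((seq_len(nr) - (nr + 1) / 2)^2, (seq_len(nc) - (nc + 1) / 2)^2,
                   `+`) <= (0.4 * min(nr, nc))^2
  depth <- 1 - stats::quantile(brightfield[central], 0.001) /
    stats::median(brightfield[central])
  x <- norm01(max(brightfield) - brightfield)   # worms bright after inversion
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  mask <- if (depth < params$min_contrast) x > 1 else x > thr
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  n_comp <- max(lab)
  empty <- list(labels = matrix(0L, nrow(x), ncol(x)),
                objects = tibble::tibble(id = integer(), area = numeric(),
                                         multiplicity = integer(),
                                         row = numeric(), col = numeric()),
                reference_area = params$reference_worm_area, threshold = thr)
  if (n_comp == 0) return(empty)
  area <- tabulate(lab[lab > 0], nbins = n_comp)
  cand <- which(area >= params$min_area)
  if (!length(cand)) return(empty)
  ref <- if (params$estimate_reference) {
    med_all <- stats::median(area[cand])
    singles <- cand[area[cand] <= params$single_area_mult * med_all]
    if (length(singles)) stats::median(area[singles]) else params$reference_worm_area
  } else {
    params$reference_worm_area
  }
  keep <- cand[area[cand] <= params$max_area_mult * ref]
  if (!length(keep)) return(empty)
  mult <- ifelse(area[keep] <= params$single_area_mult * ref, 1L,
                 pmax(1L, as.integer(round(area[keep] / ref))))
  cent <- component_centroids(lab, keep)
  labels_out <- lab
  labels_out[!(lab %in% keep)] <- 0L
  list(
    labels = labels_out,
    objects = tibble::tibble(
      id = as.integer(keep),
      area = area[keep],
      multiplicity = mult,
      row = cent$row,
      col = cent$col
    ),
    reference_area = ref,
    threshold = thr
  )
}

#' Count fluorescent child objects inside each segmented worm
#'
#' Thresholds the fluorescence channel, labels connected fluorescent
#' components, and assigns each component to the worm object containing its
#' centroid. The threshold is the larger of Otsu's value and a robust
#' background guard (`median + 10 * mad`), so an image with no fluorescent
#' worms yields no spurious children from noise. Components whose centroid
#' lies on background are reported as unassigned.
#'
#' @param segmentation Output of [segment_worms()].
#' @param fluorescence Fluorescence matrix in the same frame as the
#'   segmented brightfield.
#' @param params A [segmentation_params()] (uses `min_gfp_area`).
#' @return A list: `children` tibble (`id`, `n_children`) covering every
#'   segmented object, `n_unassigned`, `threshold`.
#' @export
detect_gfp_children <- function(segmentation, fluorescence,
                                params = segmentation_params()) {
  labels <- segmentation$labels
  if (!identical(dim(labels), dim(fluorescence))) {
    stop("fluorescence frame does not match the segmented brightfield frame", call. = FALSE)
  }
  objects <- segmentation$objects
  y <- norm01(fluorescence)
  thr <- max(EBImage::otsu(EBImage::Image(y), range = c(0, 1)),
             stats::median(y) + 10 * stats::mad(y))
  mask <- y > thr
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  n_comp <- max(lab)
  children <- tibble::tibble(id = objects$id,
                             n_children = integer(length(objects$id)))
  if (n_comp == 0) {
    return(list(children = children, n_unassigned = 0L, threshold = thr))
  }
  area <- tabulate(lab[lab > 0], nbins = n_comp)
  comp <- which(area >= params$min_gfp_area)
  if (!length(comp)) {
    return(list(children = children, n_unassigned = 0L, threshold = thr))
  }
  cent <- component_centroids(lab, comp)
  cr <- pmin(pmax(round(cent$row), 1L), nrow(labels))
  cc <- pmin(pmax(round(cent$col), 1L), ncol(labels))
  host <- labels[cbind(cr, cc)]
  n_unassigned <- sum(host == 0L)
  counts <- table(factor(host[host > 0L], levels = objects$id))
  children$n_children <- as.integer(counts)
  list(children = children, n_unassigned = n_unassigned, threshold = thr)
}

#' End-to-end worm counting of one well-image pair
#'
#' Runs illumination correction, cropping, worm segmentation, and GFP child
#' detection, then assembles the dual-channel counts: clump multiplicities
#' count toward the total, and a clump's GFP children are attributed to at
#' most its multiplicity of worms. A worm object with no GFP child is the
#' focal genotype; one or more children mark it as the competitor.
#'
#' @param pair A `well_image_pair` (rendered or read from file).
#' @param crop_fraction Border crop applied to both channels; default 0.
#' @param params A [segmentation_params()].
#' @param illum_sigma Gaussian scale for illumination correction; default
#'   1/16 of the smaller image dimension.
#' @return A list: `count` (`n_total`, `n_gfp`, `crop_fraction`,
#'   `n_unassigned_gfp`, per-object `objects` detail with child counts and
#'   multiplicities, and the parameter block used), and `estimate`
#'   (tibble with `p`, `ci`, `log_ci`; all `NA` for an empty well).
#' @export
count_image_pair <- function(pair, crop_fraction = 0,
                             params = segmentation_params(),
                             illum_sigma = NULL) {
  stopifnot(inherits(pair, "well_image_pair") ||
              (is.list(pair) && all(c("brightfield", "fluorescence") %in% names(pair))))
  bf <- pair$brightfield
  fl <- pair$fluorescence
  if (!identical(dim(bf), dim(fl))) stop("channel dimensions differ", call. = FALSE)
  if (is.null(illum_sigma)) illum_sigma <- min(dim(bf)) / 16
  bf <- correct_illumination(bf, sigma = illum_sigma)
  bf <- crop_well(bf, crop_fraction)
  fl <- crop_well(fl, crop_fraction)
  seg <- segment_worms(bf, params)
  kids <- detect_gfp_children(seg, fl, params)
  objects <- dplyr::left_join(seg$objects, kids$children, by = "id")
  # each GFP child is a distinct worm's locus, so a clump holds at least as
  # many worms as it has children; area quantization provides the rest
  objects$multiplicity <- pmax(objects$multiplicity, objects$n_children)
  gfp_worms <- pmin(objects$n_children, objects$multiplicity)
  n_total <- sum(objects$multiplicity)
  n_gfp <- sum(gfp_worms)
  est <- if (n_total > 0) {
    p <- (n_total - n_gfp) / n_total
    tibble::tibble(p = p,
                   ci = ifelse(p < 1, p / (1 - p), NA_real_),
                   log_ci = ifelse(p > 0 & p < 1, log(p / (1 - p)), NA_real_))
  } else {
    tibble::tibble(p = NA_real_, ci = NA_real_, log_ci = NA_real_)
  }
  list(
    count = list(n_total = as.integer(n_total), n_gfp = as.integer(n_gfp),
                 crop_fraction = crop_fraction,
                 n_unassigned_gfp = kids$n_unassigned,
                 objects = objects,
                 reference_area = seg$reference_area,
                 params = params),
    estimate = est
  )
}
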