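test_that("illumination correction flattens a radial field inside the well", {
  nr <- 200; cy <- (nr + 1) / 2
  rad2 <- outer((1:nr - cy)^2, (1:nr - cy)^2, `+`) / (0.47 * nr)^2
  img <- 0.8 * (1 - 0.35 * rad2)  # flat scene under a smooth radial gradient
  corr <- correct_illumination(img)
  sigma <- min(dim(img)) / 16
  b <- ceiling(2 * sigma)  # the windowed estimate is unreliable within ~2 sigma of the border
  inner <- matrix(FALSE, nr, nr); inner[(b + 1):(nr - b), (b + 1):(nr - b)] <- TRUE
  reg <- (rad2 <= 1) & inner
  rel <- abs(corr[reg] - mean(corr[reg])) / mean(corr[reg])
  expect_lt(max(rel), 0.02)
  # already-flat image: unchanged up to normalization
  flat <- matrix(0.7, 60, 60) + matrix(rnorm(3600, 0, 1e-4), 60, 60)
  cf <- correct_illumination(flat)
  expect_lt(max(abs(cf - flat)), 1e-3)
  expect_warning(correct_illumination(matrix(1, 10, 10)), "constant")
})

test_that("rendered wells become radially flat after correction", {
  blank <- render_well_image(0, 0, render_config(debris_rate = 0), seed = 1)
  corr <- correct_illumination(blank$brightfield)
  d <- dim(corr); cy <- d[1] / 2; cx <- d[2] / 2
  rad <- sqrt(outer((seq_len(d[1]) - cy)^2, (seq_len(d[2]) - cx)^2, `+`))
  wr <- 0.47 * min(d)
  center <- mean(corr[rad < 0.2 * wr])
  edge <- mean(corr[rad > 0.85 * wr & rad < 0.98 * wr])
  expect_gt(edge / center, 0.95)
  expect_lt(edge / center, 1.05)
  # before correction the edge really is darker
  raw <- blank$brightfield
  expect_lt(mean(raw[rad > 0.85 * wr & rad < 0.98 * wr]) / mean(raw[rad < 0.2 * wr]), 0.8)
})

test_that("cropping removes the requested border and nothing else", {
  img <- matrix(runif(10000), 100, 100)
  expect_identical(crop_well(img, 0), img)
  expect_equal(dim(crop_well(img, 0.1)), c(80L, 80L))
  expect_error(crop_well(img, 0.5), "crop_fraction")
  expect_error(crop_well(matrix(1, 5, 5), 0.45), "too large")
})

test_that("segmentation counts disjoint worms, quantizes clumps, filters specks", {
  # five disjoint bars
  bars <- lapply(seq(10, 90, by = 20), function(r) list(rows = r:(r + 4), cols = 20:69))
  p5 <- bar_pair(bars = bars)
  seg <- segment_worms(p5$brightfield)
  expect_equal(nrow(seg$objects), 5L)
  expect_true(all(seg$objects$multiplicity == 1L))
  # one clump of three touching bars: single component, multiplicity 3
  clump <- bar_pair(bars = list(list(rows = 30:42, cols = 30:79)))
  segc <- segment_worms(clump$brightfield,
                        segmentation_params(reference_worm_area = 250,
                                            estimate_reference = FALSE))
  expect_equal(nrow(segc$objects), 1L)
  expect_equal(segc$objects$multiplicity, 3L)
  expect_equal(segc$objects$area, 13L * 50L)
  # sub-threshold specks are not worms
  specks <- bar_pair(bars = lapply(1:6, function(i) list(rows = (10 * i):(10 * i + 1),
                                                         cols = 50:53)))
  expect_equal(nrow(segment_worms(specks$brightfield)$objects), 0L)
})

test_that("GFP children are assigned by centroid containment", {
  pr <- bar_pair(bars = list(list(rows = 40:44, cols = 20:69),
                             list(rows = 70:74, cols = 20:69)),
                 gfp_at = list(list(row = 42, col = 30),   # inside worm 1
                               list(row = 20, col = 100))) # background blob
  seg <- segment_worms(pr$brightfield)
  kids <- detect_gfp_children(seg, pr$fluorescence)
  expect_equal(sum(kids$children$n_children), 1L)
  expect_equal(kids$n_unassigned, 1L)
  expect_error(detect_gfp_children(seg, pr$fluorescence[1:50, ]), "frame")
})

test_that("a GFP locus in the cropped-off head region yields a focal false negative", {
  # worm spans the left edge; its locus sits in the region a 0.1 crop removes
  pr <- bar_pair(nr = 100, nc = 100,
                 bars = list(list(rows = 48:52, cols = 3:60),
                             list(rows = 20:24, cols = 30:79)),
                 gfp_at = list(list(row = 50, col = 6)))
  res <- count_image_pair(pr, crop_fraction = 0.1)
  expect_equal(res$count$n_total, 2L)
  expect_equal(res$count$n_gfp, 0L)  # the truncated worm reads as focal
  res0 <- count_image_pair(pr, crop_fraction = 0)
  expect_equal(res0$count$n_gfp, 1L)
})

test_that("end-to-end counting is exact with clumping and debris off", {
  cfg <- render_config(clump_prob = 0, debris_rate = 0)
  pair <- render_well_image(20, 0.4, cfg, seed = 3)
  expect_equal(nrow(pair$truth), 20L)
  expect_equal(sum(pair$truth$is_gfp), 8L)
  res <- count_image_pair(pair)
  expect_equal(res$count$n_total, 20L)
  expect_equal(res$count$n_gfp, 8L)
  expect_equal(res$estimate$p, 0.6)
  # empty well
  empty <- render_well_image(0, 0, render_config(debris_rate = 0), seed = 2)
  res0 <- count_image_pair(empty)
  expect_equal(res0$count$n_total, 0L)
  expect_true(is.na(res0$estimate$p))
  # rendering is reproducible and refuses impossible packing
  expect_identical(render_well_image(10, 0.5, cfg, seed = 5)$brightfield,
                   render_well_image(10, 0.5, cfg, seed = 5)$brightfield)
  expect_error(render_well_image(500, 0.5, render_config(width = 96, height = 96,
                                                         clump_prob = 0), seed = 1),
               "packing")
})

test_that("counting is invariant to global intensity rescaling of either channel", {
  pair <- render_well_image(15, 0.4, render_config(clump_prob = 0, debris_rate = 0),
                            seed = 6)
  res <- count_image_pair(pair)
  scaled <- pair
  scaled$brightfield <- pair$brightfield * 3.7
  scaled$fluorescence <- pair$fluorescence * 0.4
  res2 <- count_image_pair(scaled)
  expect_equal(res2$count$n_total, res$count$n_total)
  expect_equal(res2$count$n_gfp, res$count$n_gfp)
})

test_that("worm-sized debris inflates p and cropping walks it back", {
  # debris is never fluorescent, so adding it can only raise the focal share
  mean_p <- function(debris_rate, crop = 0) {
    cf <- render_config(clump_prob = 0, debris_rate = debris_rate,
                        debris_area = 180, debris_edge_bias = 0.65)
    mean(vapply(1:8, function(s) {
      count_image_pair(render_well_image(24, 0.5, cf, seed = s),
                       crop_fraction = crop)$estimate$p
    }, numeric(1)))
  }
  p_levels <- c(mean_p(0), mean_p(10), mean_p(25))
  expect_true(all(diff(p_levels) >= 0))
  # on debris-laden wells, estimated p decreases as the crop grows
  crops <- vapply(c(0, 0.1, 0.2), function(cr) mean_p(20, cr), numeric(1))
  expect_true(all(diff(crops) < 0))
})
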