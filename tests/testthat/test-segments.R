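test_that("RoI tiling produces full 400-pixel segments anchored top-left", {
  img <- confocal_image(matrix(100, 100, 100), 0.06, detector_model())
  segs <- segment_rois(img, rect_roi(10, 10, 60, 60))
  expect_identical(nrow(segs), 9L)
  expect_true(all(segs$n_px == 400L))
  expect_identical(min(segs$row0), 10L)   # anchored at the bounding box
  expect_identical(min(segs$col0), 10L)
  # too small for one tile: zero segments plus a warning
  expect_warning(none <- segment_rois(img, rect_roi(0, 0, 19, 19)),
                 "too small")
  expect_identical(nrow(none), 0L)
  # a triangle keeps only tiles fully inside the polygon
  tri <- tibble::tibble(name = "tri",
                        vertices = list(cbind(c(0, 99, 0), c(0, 99, 99))))
  segs_tri <- segment_rois(img, tri)
  expect_gt(nrow(segs_tri), 0)
  mask <- rasterize_polygon(tri$vertices[[1]], 100, 100)
  for (k in seq_len(nrow(segs_tri))) {
    rows <- segs_tri$row0[k] + 1:20
    cols <- segs_tri$col0[k] + 1:20
    expect_true(all(mask[rows, cols]))
  }
})

test_that("masked pixels exclude their segments from the tiling", {
  img <- confocal_image(matrix(100, 60, 60), 0.06, detector_model())
  mask <- matrix(FALSE, 60, 60)
  mask[25, 25] <- TRUE  # one masked pixel kills exactly one tile
  segs <- segment_rois(img, mask = mask)
  expect_identical(nrow(segs), 8L)
})

test_that("single-Gaussian segment fits recover known histogram parameters", {
  set.seed(17)
  px <- rnorm(400, 500, 50)
  fit <- fit_segment_histogram(px)
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$mean_i / 500 - 1), 0.02)
  expect_lt(abs(fit$sd_i / 50 - 1), 0.10)
  # constant segment: no fit
  expect_false(fit_segment_histogram(rep(7, 400))$fit_ok)
})

test_that("fitted parameters track sample moments for unimodal segments", {
  hits <- 0L
  n_rep <- 300L
  for (s in seq_len(n_rep)) {
    set.seed(s)
    px <- rnorm(400, 800, 120)
    fit <- fit_segment_histogram(px)
    ok <- fit$fit_ok &&
      abs(fit$mean_i / mean(px) - 1) < 0.05 &&
      abs(fit$sd_i / sd(px) - 1) < 0.05
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("effective brightness scales with oligomer size", {
  det <- detector_model()
  st1 <- segment_stats(sim_pure_image(1, 40, shape_px = c(240L, 240L),
                                      seed = 31))
  st2 <- segment_stats(sim_pure_image(2, 40, shape_px = c(240L, 240L),
                                      seed = 32))
  expect_lt(abs(mean(st1$eps_eff, na.rm = TRUE) / 205 - 1), 0.10)
  expect_lt(abs(mean(st2$eps_eff, na.rm = TRUE) / 410 - 1), 0.10)
  # spectrogram peak position mirrors the monomer reference line
  expect_lt(abs(median(st1$eps_eff, na.rm = TRUE) / 205 - 1), 0.10)
  # noise-only segment is excluded
  noise_sd <- sqrt(det$read_noise_sd^2 + det$background_sd^2)
  eps <- effective_brightness(mean_i = det$offset + det$background_mean,
                              sd_i = noise_sd, detector = det)
  expect_true(is.na(eps))
  expect_error(effective_brightness(100, 10, det, gamma = 0), "0, 1")
})

test_that("segment concentration is composition-invariant and unbiased in range", {
  st1 <- segment_stats(sim_pure_image(1, 40, shape_px = c(240L, 240L),
                                      seed = 41))
  st4 <- segment_stats(sim_pure_image(4, 40, shape_px = c(240L, 240L),
                                      seed = 42))
  c1 <- mean(st1$concentration, na.rm = TRUE)
  c4 <- mean(st4$concentration, na.rm = TRUE)
  expect_lt(abs(c4 / c1 - 1), 0.05)      # all-monomer vs all-tetramer
  expect_lt(abs(c1 / 40 - 1), 0.10)
  # relative bias < 10% across the working density range
  for (dens in c(15, 60, 100)) {
    st <- segment_stats(sim_pure_image(1, dens, shape_px = c(200L, 200L),
                                       seed = 50 + dens))
    expect_lt(abs(mean(st$concentration, na.rm = TRUE) / dens - 1), 0.10)
  }
  # zero signal maps to zero concentration
  det <- detector_model()
  expect_equal(segment_concentration(det$offset + det$background_mean, det), 0)
})

test_that("despot masks punctae with few false positives", {
  img <- sim_pure_image(1, 40, shape_px = c(240L, 240L), seed = 61)
  # puncta-free image: almost nothing masked
  clean <- despot(img)
  expect_lt(mean(clean$mask), 0.01)
  # contaminated image: most puncta pixels masked, few clean pixels masked
  cont <- add_punctae(img, puncta_spec(), seed = 62)
  ds <- despot(cont$image)
  expect_gte(sum(ds$mask & cont$mask) / sum(cont$mask), 0.80)
  expect_lte(sum(ds$mask & !cont$mask) / sum(!cont$mask), 0.05)
  # pixels are masked, not inpainted
  expect_identical(ds$image$data, cont$image$data)
  # brightness recovers once the mask is applied
  eps_clean <- mean(segment_stats(img)$eps_eff, na.rm = TRUE)
  eps_desp <- mean(segment_stats(cont$image, mask = ds$mask)$eps_eff,
                   na.rm = TRUE)
  expect_lt(abs(eps_desp / eps_clean - 1), 0.15)
})
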