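test_that("QB calibration recovers gamma * q0 from a simulated monomer series", {
  ser <- simulate_calibration_series(densities = c(40, 62.5), seeds = 1:2,
                                     shape_px = c(256L, 256L))
  qb <- estimate_quantal_brightness(lapply(ser, `[[`, "image"), roi_px = 64L)
  expect_s3_class(qb, "qb_calibration")
  expect_lt(abs(qb$mean_qb / (0.5 * 205) - 1), 0.05)
  expect_gt(qb$meu_boundary, 1)
  # glance/tidy surface
  g <- glance(qb)
  expect_identical(g$n_roi, qb$n_roi)
  expect_true(all(c("qb", "meu", "excluded") %in% names(tidy(qb))))
})

test_that("QB is density-invariant across the calibration range", {
  ser <- simulate_calibration_series(densities = c(20, 50, 100), seeds = 4:6,
                                     shape_px = c(256L, 256L))
  per_density <- vapply(ser, function(s) {
    estimate_quantal_brightness(s$image, roi_px = 64L)$mean_qb
  }, 0)
  expect_lt(diff(range(per_density)) / mean(per_density), 0.10)
})

test_that("a pure-noise image fails QB calibration", {
  set.seed(9)
  noise <- matrix(round(rnorm(64^2, 50, 15) + rnorm(64^2, 0, 20)), 64, 64)
  img <- confocal_image(pmax(noise, 0), 0.06, detector_model())
  expect_error(suppressWarnings(estimate_quantal_brightness(img, roi_px = 32L)),
               "all RoIs excluded")
})

test_that("MEU conversion and classification follow their definitions", {
  expect_equal(meu_convert(113.5, 113.5), 1.0)
  expect_equal(meu_convert(227.0, 113.5), 2.0)
  expect_identical(meu_convert(numeric(0), 113.5), numeric(0))
  expect_identical(meu_convert(c(100, 150, 120), 100),
                   c(1.0, 1.5, 1.2))          # order preserved
  expect_error(meu_convert(c(1, 2), 0), "positive")

  expect_equal(meu_boundary(113.5, 13.2), 1.228)
  expect_lt(abs(meu_boundary(113.5, 13.2) - 1.227), 0.002)
  expect_equal(meu_boundary(100, 0), 1.000)
  expect_equal(meu_boundary(200, 20.408), 1.200)
  expect_error(meu_boundary(-1, 2), "positive")

  expect_identical(as.character(classify_meu(1.0, 1.227)), "monomeric")
  expect_identical(as.character(classify_meu(1.227, 1.227)), "monomeric")
  expect_identical(as.character(classify_meu(2.0, 1.227)), "higher_order")
  expect_error(classify_meu(1, 0.9), "> 1")
})

test_that("the D'Agostino-Pearson omnibus statistic matches an independent implementation", {
  # frozen reference values computed with scipy.stats.normaltest
  set.seed(42)
  x <- round(rnorm(50, 100, 15), 6)
  dp <- dagostino_pearson(x)
  expect_equal(dp$statistic, 0.6863994074, tolerance = 1e-8)
  expect_equal(dp$p.value, 0.7094965083, tolerance = 1e-8)
  set.seed(7)
  y <- round(rexp(40, 1), 6)
  dp2 <- dagostino_pearson(y)
  expect_equal(dp2$statistic, 24.2120726800, tolerance = 1e-8)
  expect_equal(dp2$p.value, 0.0000055261, tolerance = 1e-4)
  # strongly platykurtic (bimodal) sample: signed cube root branch
  set.seed(99)
  b <- round(c(rnorm(300, 1, 0.1), rnorm(300, 2, 0.1)), 6)
  dp3 <- dagostino_pearson(b)
  expect_equal(dp3$statistic, 2697.6396766008, tolerance = 1e-8)
  expect_lt(dp3$p.value, 1e-100)
  expect_error(dagostino_pearson(rep(1, 20)), "constant")
  expect_error(dagostino_pearson(1:5), "n >= 8")
})

test_that("normality report accepts Gaussian MEUs and rejects bimodal ones", {
  set.seed(31)
  good <- normality_report(rnorm(1000, 1, 0.12))
  expect_true(all(good$tests$p_value > 0.05))
  # two modes at 1 and 2 MEU
  bad <- normality_report(c(rnorm(500, 1, 0.1), rnorm(500, 2, 0.1)))
  expect_true(all(bad$tests$p_value < 0.05))
  # histogram uses 0.2-MEU bins
  expect_equal(unique(round(diff(good$histogram$bin_low), 10)), 0.2)
  # insufficient n: no tests, explicit note
  small <- normality_report(c(0.9, 1.0, 1.1, 1.2))
  expect_null(small$tests)
  expect_match(small$note, "insufficient n")
  expect_error(normality_report(rep(1, 50)), "constant")
})

test_that("concentration from intensity implements the SpIDA conversion", {
  expect_equal(concentration_from_intensity(1135, qb = 113.5, gamma = 0.5,
                                            psf_area_um2 = 0.111),
               10 * 0.5 / 0.111, tolerance = 1e-10)
  expect_equal(concentration_from_intensity(0, qb = 113.5), 0)
  expect_warning(
    out <- concentration_from_intensity(-5, qb = 113.5), "negative")
  expect_identical(out, 0)
  expect_error(concentration_from_intensity(100, qb = -1), "positive")
  expect_error(concentration_from_intensity(100, qb = 10, gamma = 1.5),
               "0, 1")
})

test_that("SpIDA concentration round-trips a simulated density", {
  img <- sim_pure_image(1, 40, shape_px = c(256L, 256L), seed = 21)
  det <- detector_model()
  mu_c <- mean(img$data) - det$offset - det$background_mean
  conc <- concentration_from_intensity(mu_c, qb = 0.5 * 205, gamma = 0.5,
                                       psf_area_um2 = psf_area(0.2656))
  expect_lt(abs(conc / 40 - 1), 0.10)
})
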