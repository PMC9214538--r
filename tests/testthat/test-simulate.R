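test_that("molecule field honours densities and bookkeeping", {
  # zero density -> empty field
  f0 <- simulate_molecule_field(species_mixture(1, 0), 10, 10, seed = 1)
  expect_identical(nrow(f0), 0L)
  # Poisson count at C = 50/um^2 over 100 um^2 within 4 SD of 5000
  f <- simulate_molecule_field(species_mixture(1, 50), 10, 10, seed = 2)
  expect_lt(abs(nrow(f) - 5000), 4 * sqrt(5000))
  # 50/50 monomer/dimer: protomer total is an exact bookkeeping identity
  f2 <- simulate_molecule_field(species_mixture(c(1, 2), c(20, 10)), 8, 8,
                                seed = 3)
  expect_identical(sum(f2$size),
                   sum(f2$size == 1) + 2L * sum(f2$size == 2))
  expect_error(simulate_molecule_field(species_mixture(1, 5), 0, 10, 1),
               "positive")
})

test_that("field simulation and rendering are seed-deterministic", {
  mx <- species_mixture(c(1, 2), c(10, 5))
  f1 <- simulate_molecule_field(mx, 6, 6, seed = 11)
  f2 <- simulate_molecule_field(mx, 6, 6, seed = 11)
  expect_identical(f1, f2)
  i1 <- render_image(f1, shape_px = c(100, 100), seed = 4)
  i2 <- render_image(f2, shape_px = c(100, 100), seed = 4)
  expect_identical(i1$data, i2$data)
  i3 <- render_image(f1, shape_px = c(100, 100), seed = 5)
  expect_false(identical(i1$data, i3$data))
})

test_that("rendered images follow the stated image-formation model", {
  # no molecules, no noise: constant image at the offset
  empty <- tibble::tibble(x_um = double(), y_um = double(), size = integer())
  img <- render_image(empty, detector = quiet_detector(100),
                      shape_px = c(32, 32), seed = 1)
  expect_true(all(img$data == 100))
  # an isolated molecule centred on a pixel peaks at offset + m * q0
  for (m in c(1L, 3L)) {
    fld <- tibble::tibble(x_um = 10.5 * 0.06, y_um = 12.5 * 0.06, size = m)
    img <- render_image(fld, detector = quiet_detector(100),
                        shape_px = c(24, 24), seed = 1)
    expect_equal(max(img$data), 100 + m * 205, tolerance = 1e-2)
    expect_identical(which.max(img$data),
                     which(row(img$data) == 13 & col(img$data) == 11))
  }
})

test_that("closed-form moments have the stated algebraic structure", {
  det <- detector_model()
  # empty mixture: noise only
  m0 <- closed_form_moments(species_mixture(1, 0), detector = det)
  expect_equal(m0$expected_mean, det$offset + det$background_mean)
  expect_equal(m0$expected_variance,
               det$read_noise_sd^2 + det$background_sd^2)
  # pure monomer: excess variance over corrected mean = gamma * q0
  m1 <- closed_form_moments(species_mixture(1, 40), detector = det)
  expect_equal((m1$expected_variance - m0$expected_variance) /
                 (m1$expected_mean - m0$expected_mean), 0.5 * 205)
  # dimers at the same protomer density: same mean, twice the excess variance
  m2 <- closed_form_moments(species_mixture(2, 20), detector = det)
  expect_equal(m2$expected_mean, m1$expected_mean)
  expect_equal(m2$expected_variance - m0$expected_variance,
               2 * (m1$expected_variance - m0$expected_variance))
})

test_that("rendered pixel moments match the closed-form oracle", {
  mixtures <- list(species_mixture(1, 40),
                   species_mixture(2, 20),
                   species_mixture(4, 10),
                   species_mixture(c(1, 2), c(20, 10)),
                   species_mixture(c(1, 2, 4), c(10, 7.5, 3.75)))
  n_img <- 8
  for (k in seq_along(mixtures)) {
    mx <- mixtures[[k]]
    mom <- closed_form_moments(mx)
    means <- vars <- numeric(n_img)
    for (i in seq_len(n_img)) {
      fld <- fifspec:::field_with_margin(mx, c(160L, 160L), 0.06, 1,
                                         seed = 100 * k + i)
      img <- render_image(fld, shape_px = c(160L, 160L),
                          seed = 100 * k + i + 50)
      means[i] <- mean(img$data)
      vars[i] <- var(as.vector(img$data))
    }
    expect_lt(abs(mean(means) - mom$expected_mean),
              3 * sd(means) / sqrt(n_img))
    expect_lt(abs(mean(vars) - mom$expected_variance),
              3 * sd(vars) / sqrt(n_img))
  }
})

test_that("punctae contamination behaves as specified", {
  img <- sim_pure_image(1, 40, shape_px = c(160L, 160L), seed = 5)
  # zero density: unchanged, empty mask
  out0 <- add_punctae(img, puncta_spec(count_density = 0), seed = 1)
  expect_identical(out0$image$data, img$data)
  expect_false(any(out0$mask))
  # zero amplitude: image unchanged, footprint mask may be non-empty
  outz <- add_punctae(img, puncta_spec(intensity_scale = 0), seed = 2)
  expect_identical(outz$image$data, img$data)
  # default spec: masked pixels are brighter on average
  out <- add_punctae(img, puncta_spec(), seed = 3)
  expect_true(any(out$mask))
  expect_gt(mean(out$image$data[out$mask]), mean(out$image$data[!out$mask]))
})

test_that("calibration series covers the range and flags the density floor", {
  ser <- simulate_calibration_series(densities = c(12.5, 20, 100),
                                     seeds = 1:3, shape_px = c(64L, 64L))
  expect_length(ser, 3)
  for (s in ser) {
    expect_s3_class(s$image, "confocal_image")
    expect_identical(s$manifest$mixture$sizes, 1L)
    expect_identical(s$manifest$total_protomers, s$manifest$n_molecules)
  }
  expect_match(ser[[1]]$manifest$flags, "below reliable calibration floor")
  expect_length(ser[[2]]$manifest$flags, 0)
})
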