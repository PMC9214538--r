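make_stats <- function(eps, conc) {
  tibble::tibble(roi = "r", segment = seq_along(eps), row0 = 0L, col0 = 0L,
                 mean_i = NA_real_, sd_i = NA_real_, fit_mean = NA_real_,
                 fit_sd = NA_real_, fit_ok = TRUE, eps_eff = eps,
                 concentration = conc, reason = NA_character_)
}

test_that("spectrogram binning is half-open and floor-respecting", {
  st <- make_stats(rep(205, 100), rep(30, 100))
  sp <- build_spectrogram(st)
  expect_identical(sum(sp$n_segments), 100L)
  expect_identical(sp$n_segments[sp$bin_low == 25], 100L)
  # a segment exactly on an edge joins the upper bin
  sp2 <- build_spectrogram(make_stats(205, 25))
  expect_identical(sp2$n_segments[sp2$bin_low == 25], 1L)
  expect_identical(sp2$n_segments[sp2$bin_high == 25], 0L)
  # below the 15 protomers/um^2 floor: never binned
  expect_warning(sp3 <- build_spectrogram(make_stats(c(205, 205), c(10, 14.9))),
                 "no segments")
  expect_identical(sum(sp3$n_segments), 0L)
  # at/above the top edge: excluded as well
  expect_warning(sp4 <- build_spectrogram(make_stats(205, 65)), "no segments")
  expect_identical(sum(sp4$n_segments), 0L)
  expect_warning(build_spectrogram(make_stats(numeric(0), numeric(0))),
                 "no segments")
  # low-n flag
  sp5 <- build_spectrogram(make_stats(rep(205, 5), rep(30, 5)))
  expect_true(sp5$low_n[sp5$bin_low == 25])
})

test_that("simulated binned counts match the ground truth within Poisson error", {
  cond <- simulate_condition(1, 0, 0, n_replicates = 1,
                             densities = c(30, 40, 50),
                             shape_px = c(240L, 240L), seed = 400)
  st <- dplyr::bind_rows(lapply(cond[[1]], segment_stats))
  sp <- build_spectrogram(st)
  # each density lands overwhelmingly in its own bin
  for (b in c(25, 35, 45)) {
    n <- sp$n_segments[sp$bin_low == b]
    expect_gt(n, 144 - 4 * sqrt(144))   # 12x12 segments per field
    expect_lt(n, 144 + 4 * sqrt(144))
  }
})

test_that("pure-species synthetic spectrograms are recovered with protomer weighting", {
  set.seed(77)
  # all monomer
  fr1 <- fit_oligomer_fractions(rnorm(400, 205, 30))
  expect_gte(fr1$f_monomer, 0.95)
  # 50/50 protomer-weighted monomer/dimer: entity fractions 2/3 and 1/3
  eps <- c(rnorm(400, 205, 30), rnorm(200, 410, 30 * sqrt(2)))
  fr2 <- fit_oligomer_fractions(eps)
  expect_lt(abs(fr2$f_monomer - 0.5), 0.1)
  expect_lt(abs(fr2$f_dimer - 0.5), 0.1)
  # paper-scale composition (15/40/45 protomer fractions, oligomers as 3/4-mers)
  n <- round(1200 * c(0.15, 0.40 / 2, 0.225 / 3, 0.225 / 4))
  eps3 <- c(rnorm(n[1], 205, 30), rnorm(n[2], 410, 30 * sqrt(2)),
            rnorm(n[3], 615, 30 * sqrt(3)), rnorm(n[4], 820, 60))
  fr3 <- fit_oligomer_fractions(eps3)
  expect_lt(abs(fr3$f_monomer - 0.15), 0.10)
  expect_lt(abs(fr3$f_dimer - 0.40), 0.10)
  expect_lt(abs(fr3$f_oligomer - 0.45), 0.10)
})

test_that("fractions are proper mole fractions", {
  set.seed(5)
  for (k in 1:5) {
    eps <- c(rnorm(200, 205, 40), rnorm(k * 40, 410, 60))
    for (wt in c("protomer", "count")) {
      fr <- fit_oligomer_fractions(eps, weighting = wt)
      fracs <- unlist(fr[1, c("f_monomer", "f_dimer", "f_oligomer")])
      expect_equal(sum(fracs), 1, tolerance = 1e-6)
      expect_true(all(fracs >= 0 & fracs <= 1))
    }
  }
})

test_that("underpopulated bins are skipped with a flag", {
  fr <- fit_oligomer_fractions(rnorm(10, 205, 20))
  expect_false(fr$fit_ok)
  expect_true(is.na(fr$f_monomer))
})

test_that("pooling is a segment-weighted mean over the 25-55 range", {
  fr <- structure(
    tibble::tibble(bin_low = c(15, 25, 35), bin_high = c(25, 35, 45),
                   n_segments = c(50L, 40L, 40L),
                   f_monomer = c(0.9, 0.2, 0.4), f_dimer = c(0.1, 0.5, 0.4),
                   f_oligomer = c(0.0, 0.3, 0.2), sigma1 = 30,
                   fit_ok = TRUE),
    class = c("fif_fractions", class(tibble::tibble())))
  pooled <- pool_fractions(fr)
  # the 15-25 bin lies outside the pooling range
  expect_equal(pooled$f_monomer, 0.3)
  expect_equal(pooled$f_dimer, 0.45)
  expect_equal(pooled$f_oligomer, 0.25)
  expect_equal(pooled$f_monomer + pooled$f_dimer + pooled$f_oligomer, 1)
  expect_identical(pooled$n_segments, 80L)
  # single bin in range: pooled equals that bin
  one <- pool_fractions(fr, 25, 35)
  expect_equal(one$f_monomer, 0.2)
  expect_error(pool_fractions(fr, 100, 120), "pooling range")
})
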