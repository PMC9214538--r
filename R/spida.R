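#' Quantal-brightness calibration by RoI SpIDA
#'
#' Estimates the quantal brightness (QB, a.u. per molecule) of a monomeric
#' fluorophore standard from one or more calibration images.  For each RoI
#' the noise-corrected pixel-intensity variance is divided by the
#' offset/background-corrected mean:
#' \deqn{QB = \frac{(s^2 - \sigma_{det}^2 - \sigma_{bg}^2) / (1 - v)}
#'   {\bar I - \mathrm{offset} - I_{bg}}}
#' where \eqn{v} is the finite-area correlation factor of the Gaussian-PSF
#' signal field over the RoI (the sample variance over a finite correlated
#' pixel set is biased low by the mean pairwise autocorrelation; the
#' correction makes the estimator exact under the image-formation model).
#' Under that model QB equals \eqn{\gamma q_0}.  The per-RoI values are
#' pooled into a mean and SD, from which the monomeric-equivalent-unit (MEU)
#' boundary is computed (see [meu_boundary()]).
#'
#' @param images A [confocal_image()] or list of them (e.g. the two
#'   calibration solution concentrations).
#' @param rois RoI tibble as from [read_rois()] (per image when `images` is
#'   a list of the same length, otherwise applied to every image), or `NULL`
#'   to tile each image with non-overlapping square RoIs of `roi_px` pixels.
#' @param detector A [detector_model()]; defaults to the detector stored in
#'   the first image.
#' @param psf A [psf_model()] used for the correlation correction.
#' @param roi_px Side of the square tiling RoIs when `rois = NULL`.
#' @param min_px Minimum pixels per RoI (RoIs below this are rejected).
#' @return An object of class `qb_calibration`: list with `per_roi`
#'   (tibble: image, name, n_px, mean_intensity, sd_intensity, qb, meu,
#'   excluded, reason), `mean_qb`, `sd_qb`, `meu_boundary`, `n_roi`.
#' @export
estimate_quantal_brightness <- function(images, rois = NULL, detector = NULL,
                                        psf = psf_model(), roi_px = 64L,
                                        min_px = 400L) {
  if (inherits(images, "confocal_image")) images <- list(images)
  detector <- detector %||% images[[1]]$detector
  if (is.null(detector)) abort("no detector calibration supplied.")
  per <- purrr::imap(images, function(img, i) {
    masks <- roi_masks(img, rois, roi_px)
    purrr::map2(masks, names(masks), function(mask, nm) {
      n_px <- sum(mask)
      if (n_px < min_px) {
        return(tibble(image = i, name = nm, n_px = n_px,
                      mean_intensity = NA_real_, sd_intensity = NA_real_,
                      qb = NA_real_, excluded = TRUE,
                      reason = "fewer than min_px pixels"))
      }
      px <- img$data[mask]
      v <- corr_factor(mask_or_rect(mask), psf, img$pixel_size_um)
      mu <- mean(px)
      mu_c <- mu - detector_pedestal(detector)
      var_c <- (var(px) - detector_noise_var(detector)) / (1 - v)
      # require the corrected mean to clear the shot-to-shot uncertainty of
      # a signal-free RoI, so pure-noise inputs are excluded deterministically
      if (mu_c <= 3 * sd(px) / sqrt(n_px) || var_c <= 0) {
        return(tibble(image = i, name = nm, n_px = n_px,
                      mean_intensity = mu, sd_intensity = sd(px),
                      qb = NA_real_, excluded = TRUE,
                      reason = "corrected mean or variance <= 0"))
      }
      tibble(image = i, name = nm, n_px = n_px, mean_intensity = mu,
             sd_intensity = sd(px), qb = var_c / mu_c,
             excluded = FALSE, reason = NA_character_)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (any(per$excluded))
    warn(sprintf("%d RoI(s) excluded from QB calibration.", sum(per$excluded)))
  ok <- per$qb[!per$excluded]
  if (length(ok) == 0)
    abort("all RoIs excluded: no usable signal for QB calibration.")
  mean_qb <- mean(ok); sd_qb <- sd(ok)
  per$meu <- per$qb / mean_qb
  structure(list(per_roi = per, mean_qb = mean_qb,
                 sd_qb = if (is.na(sd_qb)) 0 else sd_qb,
                 meu_boundary = meu_boundary(mean_qb,
                                             if (is.na(sd_qb)) 0 else sd_qb),
                 n_roi = length(ok)),
            class = "qb_calibration")
}

#' @export
print.qb_calibration <- function(x, ...) {
  cat(sprintf("<qb_calibration> QB = %.1f +/- %.1f (mean +/- SD, n = %d RoIs); MEU boundary %.3f\n",
              x$mean_qb, x$sd_qb, x$n_roi, x$meu_boundary))
  invisible(x)
}

# build named list of logical RoI masks for an image
roi_masks <- function(img, rois, roi_px) {
  nr <- nrow(img$data); nc <- ncol(img$data)
  if (!is.null(rois)) {
    masks <- lapply(rois$vertices, rasterize_polygon, nrow = nr, ncol = nc)
    names(masks) <- rois$name
    return(masks)
  }
  masks <- list()
  for (i in seq_len(nr %/% roi_px)) for (j in seq_len(nc %/% roi_px)) {
    m <- matrix(FALSE, nr, nc)
    m[((i - 1) * roi_px + 1):(i * roi_px), ((j - 1) * roi_px + 1):(j * roi_px)] <- TRUE
    masks[[sprintf("tile_%d_%d", i, j)]] <- m
  }
  masks
}

# pass rectangles in the cheap separable form
mask_or_rect <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  nr <- diff(range(idx[, 1])) + 1L; nc <- diff(range(idx[, 2])) + 1L
  if (nrow(idx) == nr * nc) c(nc, nr) else mask
}

#' Convert quantal-brightness values to monomeric equivalent units
#'
#' MEU = RoI QB value / reference monomeric QB; 1.0 for a pure monomer.
#'
#' @param qb_values Numeric vector of QB values (a.u./molecule).
#' @param reference_qb Reference monomeric QB (> 0), e.g. 113.5 for the
#'   mEGFP solution calibration.
#' @return Numeric vector of MEU values (order preserved).
#' @export
#' @examples
#' meu_convert(c(113.5, 227), 113.5)
meu_convert <- function(qb_values, reference_qb) {
  if (!is.numeric(reference_qb) || length(reference_qb) != 1L ||
      reference_qb <= 0)
    abort("`reference_qb` must be a single positive number.")
  qb_values / reference_qb
}

#' MEU boundary separating monomer from higher-order species
#'
#' `1 + 1.96 * (sd_qb / mean_qb)`, rounded to 3 decimals: the MEU value
#' covering 95% of a Gaussian monomer population (mean + 1.96 SD).  For the
#' mEGFP calibration (QB 113.5 +/- 13.2) this gives 1.228, matching the
#' published boundary of 1.227 to within sub-rounding ambiguity.
#'
#' @param mean_qb Mean monomer QB (> 0).
#' @param sd_qb SD of monomer QB (>= 0).
#' @return The MEU boundary (dimensionless, > 1 unless `sd_qb = 0`).
#' @export
#' @examples
#' meu_boundary(113.5, 13.2)
meu_boundary <- function(mean_qb, sd_qb) {
  if (mean_qb <= 0) abort("`mean_qb` must be positive.")
  if (sd_qb < 0) abort("`sd_qb` must be >= 0.")
  round(1 + 1.96 * sd_qb / mean_qb, 3)
}

#' Classify MEU values as monomeric or higher-order
#'
#' Monomeric iff `meu <= boundary` (boundary inclusive: the boundary is
#' defined as 95% coverage of the monomer distribution, so a value on the
#' boundary is still consistent with a monomer).
#'
#' @param meu Numeric vector of MEU values.
#' @param boundary MEU boundary (> 1), e.g. from [meu_boundary()].
#' @return Factor with levels `monomeric`, `higher_order`.
#' @export
classify_meu <- function(meu, boundary = 1.227) {
  if (boundary <= 1) abort("`boundary` must be > 1.")
  factor(ifelse(meu <= boundary, "monomeric", "higher_order"),
         levels = c("monomeric", "higher_order"))
}

#' Normality report for an MEU distribution
#'
#' Runs the D'Agostino–Pearson omnibus test and the Shapiro–Wilk test and
#' bins the values into the standard 0.2-MEU frequency histogram, as used to
#' verify that a monomer calibration yields a Gaussian MEU distribution.
#'
#' @param meus Numeric vector of MEU values.
#' @param bin_width Histogram bin width (MEU).
#' @return An object of class `meu_normality`: list with `n`, `tests`
#'   (tibble: test, statistic, p_value) and `histogram` (tibble: bin_low,
#'   bin_high, count).  With fewer than 8 values the tests are omitted and
#'   `note` says "insufficient n".
#' @export
normality_report <- function(meus, bin_width = 0.2) {
  meus <- meus[is.finite(meus)]
  n <- length(meus)
  if (n == 0) abort("no finite MEU values.")
  if (n >= 2 && sd(meus) == 0)
    abort("degenerate input: MEU values are constant.")
  breaks <- seq(floor(min(meus) / bin_width) * bin_width,
                max(meus) + bin_width, by = bin_width)
  h <- graphics::hist(meus, breaks = breaks, plot = FALSE)
  hist_tbl <- tibble(bin_low = head(h$breaks, -1), bin_high = tail(h$breaks, -1),
                     count = h$counts)
  if (n < 8) {
    return(structure(list(n = n, tests = NULL, histogram = hist_tbl,
                          note = "insufficient n"),
                     class = "meu_normality"))
  }
  dp <- dagostino_pearson(meus)
  sw <- shapiro.test(meus)
  tests <- tibble(
    test = c("dagostino_pearson", "shapiro_wilk"),
    statistic = c(dp$statistic, unname(sw$statistic)),
    p_value = c(dp$p.value, sw$p.value))
  structure(list(n = n, tests = tests, histogram = hist_tbl, note = NULL),
            class = "meu_normality")
}

#' @export
print.meu_normality <- function(x, ...) {
  cat("<meu_normality> n =", x$n, "\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n") else print(x$tests)
  invisible(x)
}

#' D'Agostino–Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness test and the Anscombe–Glynn kurtosis
#' test into the omnibus statistic \eqn{K^2 = Z_1^2 + Z_2^2}, referred to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector (n >= 8).
#' @return List with `statistic` (K²), `p.value`, `z_skewness`,
#'   `z_kurtosis`.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990) The American
#'   Statistician 44, 316–321.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson test requires n >= 8.")
  if (sd(x) == 0) abort("degenerate input: values are constant.")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  # signed cube root: the base goes negative for strongly platykurtic data
  base <- (1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4)))
  z2 <- ((1 - 2 / (9 * a)) - sign(base) * abs(base)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2)
}

#' Surface concentration from mean RoI intensity
#'
#' The SpIDA concentration estimate: the apparent number of particles per
#' beam area \eqn{N = [I] / QB} (with \eqn{[I]} the offset/background
#' corrected mean intensity) is converted to a surface density by
#' \eqn{C = N \gamma / \iint \mathrm{PSF}}.
#'
#' @param mean_intensity Corrected mean RoI intensity (a.u.); vectorised.
#' @param qb Quantal brightness (a.u./molecule, > 0).
#' @param gamma PSF shape factor in (0, 1].
#' @param psf_area_um2 PSF area integral in µm² (> 0); see [psf_area()].
#' @return Concentration in molecules/µm² (0, with a warning, where the
#'   corrected mean is negative).
#' @export
#' @examples
#' concentration_from_intensity(1135, qb = 113.5)
concentration_from_intensity <- function(mean_intensity, qb,
                                         gamma = 0.5,
                                         psf_area_um2 = psf_area(0.2656)) {
  if (qb <= 0) abort("`qb` must be positive.")
  if (psf_area_um2 <= 0) abort("`psf_area_um2` must be positive.")
  if (gamma <= 0 || gamma > 1) abort("`gamma` must be in (0, 1].")
  neg <- mean_intensity < 0
  if (any(neg, na.rm = TRUE))
    warn("negative corrected mean intensity: concentration set to 0.")
  conc <- (mean_intensity / qb) * gamma / psf_area_um2
  conc[which(neg)] <- 0
  conc
}
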