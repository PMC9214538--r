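#' Tile regions of interest into square analysis segments
#'
#' Each RoI polygon is tiled with non-overlapping `segment_px` x
#' `segment_px` squares (default 20 x 20 = 400 pixels), anchored at the
#' top-left of the RoI bounding box.  Only tiles lying fully inside the
#' polygon (and fully outside `mask`, if given) are kept; partial edge tiles
#' are discarded.
#'
#' @param image A [confocal_image()].
#' @param rois RoI tibble as from [read_rois()], or `NULL` to treat the
#'   whole frame as one rectangular RoI.
#' @param segment_px Segment side in pixels.
#' @param mask Optional logical matrix of pixels to exclude (e.g. the
#'   despot mask from [despot()]).
#' @return A tibble with one row per segment: `roi`, `segment`, `row0`,
#'   `col0` (0-based top-left corner), `n_px` and `pixels` (list column of
#'   raw pixel values).  RoIs too small for a single full tile contribute
#'   zero segments, with a warning.
#' @export
segment_rois <- function(image, rois = NULL, segment_px = 20L, mask = NULL) {
  stopifnot(inherits(image, "confocal_image"))
  nr <- nrow(image$data); nc <- ncol(image$data)
  if (is.null(rois)) {
    rois <- tibble(name = "frame",
                   vertices = list(cbind(c(0, nc, nc, 0), c(0, 0, nr, nr))))
  }
  out <- purrr::map2(rois$name, rois$vertices, function(nm, verts) {
    roi_mask <- rasterize_polygon(verts, nr, nc)
    if (!is.null(mask)) roi_mask <- roi_mask & !mask
    idx <- which(roi_mask, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      warn(sprintf("RoI '%s': no pixels inside the image.", nm))
      return(NULL)
    }
    r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
    segs <- list()
    k <- 0L
    for (i0 in seq(r0, nr - segment_px + 1L, by = segment_px)) {
      for (j0 in seq(c0, nc - segment_px + 1L, by = segment_px)) {
        rows <- i0:(i0 + segment_px - 1L)
        cols <- j0:(j0 + segment_px - 1L)
        if (!all(roi_mask[rows, cols])) next
        k <- k + 1L
        segs[[k]] <- tibble(
          roi = nm, segment = k, row0 = i0 - 1L, col0 = j0 - 1L,
          n_px = segment_px^2L,
          pixels = list(as.vector(image$data[rows, cols])))
      }
    }
    if (k == 0L)
      warn(sprintf("RoI '%s': too small for a full %dx%d segment.",
                   nm, segment_px, segment_px))
    dplyr::bind_rows(segs)
  })
  dplyr::bind_rows(out)
}

#' Fit a single Gaussian to a segment's pixel-intensity histogram
#'
#' The pixel values are binned (Freedman–Diaconis width, floored at 1 a.u.)
#' and the frequency histogram is fitted with a single Gaussian
#' `a * exp(-(x - mu)^2 / (2 s^2))` by Poisson maximum likelihood
#' (histogram counts are Poisson, so the Poisson deviance is the
#' statistically consistent fitting objective; unweighted least squares on
#' the counts would let the fitted SD wander several percent from the
#' sample moments), initialised at the sample moments.  The fit fails
#' (`fit_ok = FALSE`) for constant segments, on optimiser failure, or when
#' the fitted SD collapses below one bin width.
#'
#' @param pixels Numeric vector of segment pixel values.
#' @param bin_width Histogram bin width in a.u.; `NULL` for
#'   Freedman–Diaconis.
#' @return A one-row tibble: `mean_i`, `sd_i`, `fit_ok`.
#' @export
fit_segment_histogram <- function(pixels, bin_width = NULL) {
  mu0 <- mean(pixels); sd0 <- sd(pixels)
  if (!is.finite(sd0) || sd0 == 0)
    return(tibble(mean_i = mu0, sd_i = 0, fit_ok = FALSE))
  if (is.null(bin_width)) {
    bin_width <- max(1, 2 * stats::IQR(pixels) / length(pixels)^(1 / 3))
  }
  breaks <- seq(floor(min(pixels)) - bin_width / 2,
                max(pixels) + bin_width, by = bin_width)
  h <- graphics::hist(pixels, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  amp0 <- length(pixels) * bin_width / (sd0 * sqrt(2 * pi))
  # parameters (mu, log s, log a); Poisson negative log-likelihood
  nll <- function(p) {
    lam <- pmax(exp(p[3]) * exp(-(x - p[1])^2 / (2 * exp(2 * p[2]))), 1e-12)
    sum(lam - y * log(lam))
  }
  opt <- tryCatch(
    stats::optim(c(mu0, log(sd0), log(amp0)), nll, method = "BFGS",
                 control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(opt) || !all(is.finite(opt$par)))
    return(tibble(mean_i = mu0, sd_i = sd0, fit_ok = FALSE))
  s_hat <- exp(opt$par[2])
  tibble(mean_i = opt$par[1], sd_i = s_hat,
         fit_ok = opt$convergence == 0 && s_hat >= bin_width)
}

#' Effective molecular brightness of a segment
#'
#' \deqn{\varepsilon_{eff} = \frac{(s_I^2 - \sigma_{det}^2 - \sigma_{bg}^2)/(1 - v)}
#'   {\gamma\, (\bar I - \mathrm{offset} - I_{bg})}}
#' in a.u. per protomer: the detector-corrected intensity variance over the
#' gamma-corrected mean.  `corr_factor` is the finite-segment correlation
#' factor \eqn{v} (see [estimate_quantal_brightness()] for its role); with
#' it the estimator is exact under the simulator model, where a pure n-mer
#' field gives \eqn{\varepsilon_{eff} \to n q_0}.
#'
#' @param mean_i,sd_i Segment mean and SD (a.u.), e.g. from
#'   [fit_segment_histogram()]; vectorised.
#' @param detector A [detector_model()].
#' @param gamma PSF shape factor in (0, 1].
#' @param corr_factor Finite-segment correlation factor `v` in `[0, 1)`.
#' @return Numeric vector of effective brightness values (a.u./protomer);
#'   `NA` where the corrected mean or variance is non-positive (segment
#'   excluded).
#' @export
effective_brightness <- function(mean_i, sd_i, detector = detector_model(),
                                 gamma = 0.5, corr_factor = 0) {
  if (gamma <= 0 || gamma > 1) abort("`gamma` must be in (0, 1].")
  if (corr_factor < 0 || corr_factor >= 1) abort("`corr_factor` must be in [0, 1).")
  mu_c <- mean_i - detector_pedestal(detector)
  var_c <- (sd_i^2 - detector_noise_var(detector)) / (1 - corr_factor)
  out <- ifelse(mu_c > 0 & var_c > 0, var_c / (gamma * mu_c), NA_real_)
  out
}

#' Protomer concentration of a segment
#'
#' The corrected mean intensity converted to a surface density of protomers:
#' \eqn{C = (\bar I - \mathrm{offset} - I_{bg}) \gamma / (\gamma q_0
#' A_{PSF}) = \bar I_c / (q_0 A_{PSF})}.  Independent of the oligomeric
#' composition: only total protomer number sets the mean intensity.
#'
#' @param mean_i Segment mean intensity (a.u.); vectorised.
#' @param detector A [detector_model()].
#' @param q0 Monomeric brightness (a.u./protomer).
#' @param gamma PSF shape factor in (0, 1].
#' @param psf_area_um2 PSF area integral (µm²).
#' @return Concentration in protomers/µm² (0 with a warning where the
#'   corrected mean is negative).
#' @export
segment_concentration <- function(mean_i, detector = detector_model(),
                                  q0 = 205, gamma = 0.5,
                                  psf_area_um2 = psf_area(0.2656)) {
  if (q0 <= 0) abort("`q0` must be positive.")
  mu_c <- mean_i - detector_pedestal(detector)
  concentration_from_intensity(mu_c, qb = gamma * q0, gamma = gamma,
                               psf_area_um2 = psf_area_um2)
}

#' Mask high-intensity punctae ("despotting")
#'
#' Detects bright spots (internalised vesicles and similar contamination)
#' by a local-background-normalised threshold: a pixel is flagged when it
#' exceeds `median + k * MAD` of its RoI (whole frame when `rois = NULL`),
#' with the MAD scaled to be consistent with the SD.  The flagged set is
#' dilated by `dilate` pixels.  Flagged pixels are meant to be excluded
#' from segmentation (pass the mask to [segment_rois()]); they are not
#' inpainted and the pixel data are returned unchanged.
#'
#' @param image A [confocal_image()].
#' @param rois Optional RoI tibble; thresholds are computed per RoI.
#' @param k MAD multiplier of the threshold.
#' @param dilate Morphological dilation radius in pixels.
#' @return A list with `image` (unchanged) and `mask` (logical matrix,
#'   `TRUE` on masked pixels).
#' @export
despot <- function(image, rois = NULL, k = 5, dilate = 1L) {
  stopifnot(inherits(image, "confocal_image"))
  dat <- image$data
  nr <- nrow(dat); nc <- ncol(dat)
  mask <- matrix(FALSE, nr, nc)
  regions <- if (is.null(rois)) {
    list(matrix(TRUE, nr, nc))
  } else {
    lapply(rois$vertices, rasterize_polygon, nrow = nr, ncol = nc)
  }
  for (reg in regions) {
    px <- dat[reg]
    if (length(px) == 0) next
    thr <- median(px) + k * mad(px)
    mask[reg] <- mask[reg] | (px > thr)
  }
  if (dilate > 0 && any(mask)) {
    dil <- mask
    for (dy in -dilate:dilate) for (dx in -dilate:dilate) {
      if (dy == 0 && dx == 0) next
      r1 <- max(1, 1 + dy):min(nr, nr + dy)
      c1 <- max(1, 1 + dx):min(nc, nc + dx)
      dil[r1, c1] <- dil[r1, c1] | mask[r1 - dy, c1 - dx]
    }
    mask <- dil
  }
  list(image = image, mask = mask)
}

#' Per-segment brightness and concentration statistics
#'
#' The FIF module-2 workhorse: tiles the RoIs into 400-pixel segments
#' ([segment_rois()]), fits each segment's pixel-intensity histogram with a
#' single Gaussian ([fit_segment_histogram()]) and converts the fitted
#' moments into effective brightness and protomer concentration.
#'
#' The single-Gaussian histogram fit serves as the unimodality/quality gate
#' (`fit_ok`); the brightness and concentration estimators themselves use
#' the segment's sample moments, which coincide with the fitted parameters
#' for symmetric unimodal segments but remain unbiased under the mild
#' right-skew of shot-noise-limited pixel distributions (the fitted mode of
#' a skewed histogram sits below the mean, which would bias
#' \eqn{\varepsilon_{eff}} upward by >10% at typical densities).
#'
#' @inheritParams segment_rois
#' @param detector A [detector_model()]; defaults to the image's.
#' @param psf A [psf_model()].
#' @param q0 Monomeric brightness (a.u./protomer).
#' @param gamma PSF shape factor.
#' @return A tibble with one row per segment: `roi`, `segment`, `row0`,
#'   `col0`, `mean_i`, `sd_i` (sample moments), `fit_mean`, `fit_sd`
#'   (Gaussian-fit parameters), `fit_ok`, `eps_eff`, `concentration` and
#'   `reason` (exclusion reason code, `NA` for usable segments).
#' @export
segment_stats <- function(image, rois = NULL, detector = NULL,
                          psf = psf_model(), q0 = 205, gamma = 0.5,
                          segment_px = 20L, mask = NULL) {
  detector <- detector %||% image$detector
  if (is.null(detector)) abort("no detector calibration supplied.")
  segs <- segment_rois(image, rois, segment_px = segment_px, mask = mask)
  if (nrow(segs) == 0) {
    return(tibble(roi = character(), segment = integer(), row0 = integer(),
                  col0 = integer(), mean_i = double(), sd_i = double(),
                  fit_mean = double(), fit_sd = double(),
                  fit_ok = logical(), eps_eff = double(),
                  concentration = double(), reason = character()))
  }
  v <- corr_factor(c(segment_px, segment_px), psf, image$pixel_size_um)
  fits <- dplyr::bind_rows(purrr::map(segs$pixels, fit_segment_histogram))
  out <- dplyr::bind_cols(dplyr::select(segs, -"pixels", -"n_px"),
                          tibble(mean_i = vapply(segs$pixels, mean, 0),
                                 sd_i = vapply(segs$pixels, sd, 0),
                                 fit_mean = fits$mean_i, fit_sd = fits$sd_i,
                                 fit_ok = fits$fit_ok))
  out$eps_eff <- ifelse(out$fit_ok,
                        effective_brightness(out$mean_i, out$sd_i, detector,
                                             gamma = gamma, corr_factor = v),
                        NA_real_)
  out$concentration <- NA_real_
  usable <- which(out$fit_ok & !is.na(out$eps_eff))
  out$concentration[usable] <-
    segment_concentration(out$mean_i[usable], detector, q0 = q0,
                          gamma = gamma, psf_area_um2 = psf_area(psf$w_xy))
  out$reason <- dplyr::case_when(
    !out$fit_ok ~ "gaussian_fit_failed",
    is.na(out$eps_eff) ~ "corrected_mean_or_variance_nonpositive",
    TRUE ~ NA_character_)
  out
}
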