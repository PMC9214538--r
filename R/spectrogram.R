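#' Build a brightness spectrogram from segment statistics
#'
#' Groups the per-segment effective-brightness values into protomer
#' concentration bins.  The default bins span 15--65 protomers/µm² in steps
#' of 10, half-open `[low, high)` (a segment on a bin edge goes to the
#' higher bin); segments below the 15 protomers/µm² reliability floor of the
#' monomer calibration are excluded, as are segments at or above the top
#' edge and segments without a valid brightness estimate.
#'
#' @param stats Per-segment tibble from [segment_stats()] (needs columns
#'   `eps_eff` and `concentration`).
#' @param bin_edges Increasing vector of bin edges (protomers/µm²).
#' @param min_segments Bins with fewer segments are flagged `low_n`.
#' @return An object of class `fif_spectrogram`: a tibble with one row per
#'   bin (`bin_low`, `bin_high`, `n_segments`, `low_n`, `eps` list column),
#'   with the bin edges in the `bin_edges` attribute.
#' @export
build_spectrogram <- function(stats, bin_edges = seq(15, 65, by = 10),
                              min_segments = 20L) {
  ok <- stats[!is.na(stats$eps_eff) & !is.na(stats$concentration), ]
  lo <- head(bin_edges, -1); hi <- tail(bin_edges, -1)
  rows <- purrr::map2(lo, hi, function(l, h) {
    eps <- ok$eps_eff[ok$concentration >= l & ok$concentration < h]
    tibble(bin_low = l, bin_high = h, n_segments = length(eps),
           low_n = length(eps) < min_segments, eps = list(eps))
  })
  out <- dplyr::bind_rows(rows)
  if (sum(out$n_segments) == 0)
    warn("no segments fall inside the spectrogram bins.")
  structure(out, class = c("fif_spectrogram", class(out)),
            bin_edges = bin_edges)
}

#' @export
print.fif_spectrogram <- function(x, ...) {
  cat("<fif_spectrogram>", sum(x$n_segments), "segments in",
      nrow(x), "concentration bins\n")
  NextMethod()
}

#' Decompose brightness spectrograms into oligomer fractions
#'
#' FIF module 3: per concentration bin, the frequency histogram of
#' \eqn{\varepsilon_{eff}} is fitted by non-negative least squares with a
#' sum of Gaussians whose centres are fixed at integer multiples of the
#' monomeric brightness, \eqn{\sum_{n=1}^{n_{max}} A_n\,
#' \mathcal{N}(\varepsilon;\, n\,\varepsilon_1,\, \sigma_n)}.  Component
#' widths follow \eqn{\sigma_n = \sigma_1 \sqrt{n}} (`sigma_model =
#' "sqrt_n"`; the variance of a sum of n independent protomer signals) with
#' the monomer width \eqn{\sigma_1} profiled over a grid; amplitudes are
#' constrained non-negative.
#'
#' Two readout conventions are available.  `weighting = "protomer"`
#' (the default) reports protomer mole fractions as the size-weighted
#' normalised areas \eqn{n A_n / \sum_n n A_n}; it is the correct readout
#' when each segment is dominated by a single species, which is the classic
#' interpretation of the spectrogram.  `weighting = "count"` reports the
#' normalised areas directly; it is the appropriate readout for spatially
#' well-mixed populations, where every segment's brightness already sits at
#' the protomer-weighted mean of its local contents (see the methods
#' vignette for the analysis).  Sizes >= 3 are pooled into the oligomer
#' class.
#'
#' @param spectrogram A [build_spectrogram()] result (or a bare numeric
#'   vector of brightness values, treated as a single bin).
#' @param monomer_brightness Monomeric brightness \eqn{\varepsilon_1}
#'   (a.u./protomer, > 0); 205 for the mEGFP calibration.
#' @param n_max Largest fitted oligomer size (>= 2).
#' @param weighting Fraction readout convention (see Details).
#' @param sigma_model `"sqrt_n"` or `"prop_n"` component-width scaling.
#' @param bin_width Histogram bin width for the fit, in a.u.
#' @param sigma_grid Candidate monomer widths \eqn{\sigma_1} (a.u.).
#' @param min_segments Bins with fewer segments are skipped (`fit_ok =
#'   FALSE`).
#' @return An object of class `fif_fractions`: tibble with one row per bin
#'   (`bin_low`, `bin_high`, `n_segments`, `f_monomer`, `f_dimer`,
#'   `f_oligomer`, `sigma1`, `fit_ok`), plus the per-size areas in the
#'   `areas` attribute.
#' @export
fit_oligomer_fractions <- function(spectrogram, monomer_brightness = 205,
                                   n_max = 4L,
                                   weighting = c("protomer", "count"),
                                   sigma_model = c("sqrt_n", "prop_n"),
                                   bin_width = NULL,
                                   sigma_grid = NULL,
                                   min_segments = 20L) {
  weighting <- match.arg(weighting)
  sigma_model <- match.arg(sigma_model)
  if (monomer_brightness <= 0) abort("`monomer_brightness` must be positive.")
  if (n_max < 2) abort("`n_max` must be >= 2.")
  if (is.numeric(spectrogram)) {
    spectrogram <- tibble(bin_low = NA_real_, bin_high = NA_real_,
                          n_segments = length(spectrogram),
                          low_n = FALSE, eps = list(spectrogram))
  }
  bin_width <- bin_width %||% (monomer_brightness / 10)
  sigma_grid <- sigma_grid %||%
    seq(0.1 * monomer_brightness, 0.8 * monomer_brightness,
        by = 0.025 * monomer_brightness)
  areas <- list()
  rows <- purrr::pmap(
    list(spectrogram$bin_low, spectrogram$bin_high, spectrogram$eps),
    function(lo, hi, eps) {
      eps <- eps[is.finite(eps)]
      base <- tibble(bin_low = lo, bin_high = hi, n_segments = length(eps),
                     f_monomer = NA_real_, f_dimer = NA_real_,
                     f_oligomer = NA_real_, sigma1 = NA_real_,
                     fit_ok = FALSE)
      if (length(eps) < min_segments) return(base)
      fit <- fit_gaussian_comb(eps, monomer_brightness, n_max, sigma_model,
                               bin_width, sigma_grid)
      if (is.null(fit)) return(base)
      a <- fit$a
      frac <- switch(weighting,
                     protomer = a * seq_len(n_max) / sum(a * seq_len(n_max)),
                     count = a / sum(a))
      areas[[length(areas) + 1L]] <<- a
      base$f_monomer <- frac[1]
      base$f_dimer <- frac[2]
      base$f_oligomer <- sum(frac[3:n_max])
      base$sigma1 <- fit$sigma1
      base$fit_ok <- TRUE
      base
    })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("fif_fractions", class(out)),
            monomer_brightness = monomer_brightness, n_max = n_max,
            weighting = weighting, areas = areas)
}

# profile NNLS fit of the fixed-centre Gaussian comb to the eps histogram
fit_gaussian_comb <- function(eps, eps1, n_max, sigma_model, bin_width,
                              sigma_grid) {
  breaks <- seq(0, max(eps, (n_max + 2) * eps1) + bin_width, by = bin_width)
  eps <- eps[eps >= 0]
  h <- graphics::hist(eps, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  scale <- length(eps) * bin_width
  best <- NULL
  for (s1 in sigma_grid) {
    m <- vapply(seq_len(n_max), function(n) {
      s <- if (sigma_model == "sqrt_n") s1 * sqrt(n) else s1 * n
      dnorm(x, n * eps1, s) * scale
    }, numeric(length(x)))
    sol <- tryCatch(pracma::lsqnonneg(m, y), error = function(e) NULL)
    if (is.null(sol)) next
    sse <- sum((m %*% sol$x - y)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, a = sol$x, sigma1 = s1)
  }
  if (is.null(best) || sum(best$a) <= 0) return(NULL)
  best
}

#' Pool oligomer fractions across a concentration range
#'
#' Segment-count-weighted mean of the per-bin fractions over bins fully
#' inside `[range_low, range_high]` — the standard pooling over 25--55
#' protomers/µm², where the species fractions do not vary significantly
#' with density.
#'
#' @param fractions A `fif_fractions` tibble from
#'   [fit_oligomer_fractions()].
#' @param range_low,range_high Pooling range (protomers/µm²).
#' @return A one-row tibble: `f_monomer`, `f_dimer`, `f_oligomer`,
#'   `n_segments`, `n_bins`.
#' @export
pool_fractions <- function(fractions, range_low = 25, range_high = 55) {
  keep <- fractions$fit_ok &
    !is.na(fractions$bin_low) &
    fractions$bin_low >= range_low & fractions$bin_high <= range_high
  if (!any(keep)) abort("no fitted bins inside the pooling range.")
  f <- fractions[keep, ]
  w <- f$n_segments / sum(f$n_segments)
  tibble(f_monomer = sum(w * f$f_monomer),
         f_dimer = sum(w * f$f_dimer),
         f_oligomer = sum(w * f$f_oligomer),
         n_segments = sum(f$n_segments), n_bins = nrow(f))
}
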