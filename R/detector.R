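#' Detector calibration model
#'
#' Additive detector model used both by the forward simulator and by the
#' noise corrections in the brightness estimators: every pixel reads
#' `offset + background + read noise + signal`, with Gaussian read noise of
#' standard deviation `read_noise_sd` and a Gaussian autofluorescence
#' background of mean `background_mean` and standard deviation
#' `background_sd` (all in detector analog units, a.u.).
#'
#' The defaults are the package's simulated study conditions: zero detector
#' offset (the acquisition offset setting of the calibration imaging),
#' modest read noise and a non-zero autofluorescence background as found in
#' neuronal preparations.
#'
#' @param offset Detector offset (a.u.).
#' @param read_noise_sd Read-noise standard deviation (a.u., >= 0).
#' @param background_mean Mean background/autofluorescence level (a.u.).
#' @param background_sd Background standard deviation (a.u., >= 0).
#'
#' @return An object of class `detector_model`.
#' @export
#' @examples
#' detector_model()
detector_model <- function(offset = 0, read_noise_sd = 20,
                           background_mean = 50, background_sd = 15) {
  vals <- c(offset = as.numeric(offset),
            read_noise_sd = as.numeric(read_noise_sd),
            background_mean = as.numeric(background_mean),
            background_sd = as.numeric(background_sd))
  if (!all(is.finite(vals))) abort("detector parameters must be finite.")
  if (read_noise_sd < 0 || background_sd < 0)
    abort("`read_noise_sd` and `background_sd` must be >= 0.")
  if (offset < 0 || background_mean < 0)
    abort("`offset` and `background_mean` must be >= 0.")
  structure(as.list(vals), class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf(
    "<detector_model> offset %g, read noise SD %g, background %g +/- %g (a.u.)\n",
    x$offset, x$read_noise_sd, x$background_mean, x$background_sd))
  invisible(x)
}

# total non-signal variance and mean pedestal
detector_noise_var <- function(detector) {
  detector$read_noise_sd^2 + detector$background_sd^2
}
detector_pedestal <- function(detector) {
  detector$offset + detector$background_mean
}
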