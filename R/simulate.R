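#' Oligomer species mixture
#'
#' Defines a planar population of fluorophore-tagged oligomers: for each
#' species its size in protomers and its surface density in oligomers/µm²,
#' plus the per-protomer brightness at the beam centre.  The default
#' brightness is the mEGFP calibration value of 205 a.u./protomer
#' (gamma-corrected, thin-layer geometry).
#'
#' @param sizes Integer vector of oligomer sizes (protomers per oligomer,
#'   all >= 1).
#' @param densities Surface densities in oligomers/µm² (same length, >= 0).
#' @param q0 Brightness per protomer at the beam centre (a.u.).
#' @return An object of class `species_mixture`.
#' @export
#' @examples
#' # 50/50 monomer/dimer by protomer count, 40 protomers/um^2 total
#' mx <- species_mixture(c(1, 2), c(20, 10))
#' protomer_density(mx)
species_mixture <- function(sizes, densities, q0 = 205) {
  if (length(sizes) == 0 || length(sizes) != length(densities))
    abort("`sizes` and `densities` must be non-empty and the same length.")
  if (any(sizes < 1) || any(sizes != round(sizes)))
    abort("`sizes` must be positive integers (protomers).")
  if (any(densities < 0) || any(!is.finite(densities)))
    abort("`densities` must be finite and >= 0.")
  if (q0 <= 0) abort("`q0` must be positive.")
  structure(list(species = tibble(size = as.integer(sizes),
                                  density = as.numeric(densities)),
                 q0 = q0),
            class = "species_mixture")
}

#' @export
print.species_mixture <- function(x, ...) {
  cat("<species_mixture> q0 =", x$q0, "a.u./protomer\n")
  print(x$species)
  invisible(x)
}

#' Total protomer surface density of a mixture
#' @param mixture A [species_mixture()].
#' @return Total protomer density, protomers/µm².
#' @export
protomer_density <- function(mixture) {
  sum(mixture$species$size * mixture$species$density)
}

#' Protomer mole fractions of a mixture, pooled into monomer/dimer/oligomer
#' @param mixture A [species_mixture()].
#' @return Named numeric: `f_monomer`, `f_dimer`, `f_oligomer` (sizes >= 3).
#' @export
mixture_fractions <- function(mixture) {
  sp <- mixture$species
  p <- sp$size * sp$density
  p <- p / sum(p)
  c(f_monomer = sum(p[sp$size == 1]),
    f_dimer = sum(p[sp$size == 2]),
    f_oligomer = sum(p[sp$size >= 3]))
}

#' Build a mixture from pooled protomer mole fractions
#'
#' Convenience inverse of [mixture_fractions()]: converts target
#' monomer/dimer/oligomer protomer fractions and a total protomer density
#' into per-species oligomer densities.  The oligomer class is split equally
#' (by protomer count) between the given sizes.
#'
#' @param f_monomer,f_dimer,f_oligomer Protomer mole fractions (sum to 1).
#' @param total_density Total protomer density, protomers/µm².
#' @param oligo_sizes Sizes representing the pooled oligomer class.
#' @param q0 Brightness per protomer (a.u.).
#' @return A [species_mixture()].
#' @export
mixture_from_fractions <- function(f_monomer, f_dimer, f_oligomer,
                                   total_density, oligo_sizes = c(3, 4),
                                   q0 = 205) {
  fr <- c(f_monomer, f_dimer, f_oligomer)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    abort("fractions must be >= 0 and sum to 1.")
  sizes <- c(1, 2, oligo_sizes)
  pf <- c(f_monomer, f_dimer, rep(f_oligomer / length(oligo_sizes),
                                  length(oligo_sizes)))
  keep <- pf > 0
  species_mixture(sizes[keep], (pf * total_density / sizes)[keep], q0 = q0)
}

#' Simulate the molecule field of a planar membrane patch
#'
#' Molecule counts per species are Poisson with mean `density * area`;
#' positions are uniform i.i.d. over the rectangular field.
#'
#' @param mixture A [species_mixture()].
#' @param width_um,height_um Field dimensions in µm (> 0).
#' @param seed Integer seed; fixed seed gives an identical field.
#' @return A tibble with columns `x_um`, `y_um`, `size`.
#' @export
simulate_molecule_field <- function(mixture, width_um, height_um, seed) {
  stopifnot(inherits(mixture, "species_mixture"))
  if (width_um <= 0 || height_um <= 0)
    abort("field area must be positive.")
  set.seed(seed)
  area <- width_um * height_um
  sp <- mixture$species
  out <- purrr::pmap(sp, function(size, density) {
    n <- rpois(1L, density * area)
    tibble(x_um = runif(n, 0, width_um), y_um = runif(n, 0, height_um),
           size = rep(size, n))
  })
  dplyr::bind_rows(out)
}

#' Render a confocal image of a molecule field
#'
#' Image formation: each molecule of size `m` deposits a Gaussian PSF stamp
#' `m * q0 * exp(-2 r^2 / w_xy^2)` evaluated at pixel centres (the 60-nm
#' pixels are small relative to the 0.2656-µm waist, so point sampling is
#' accurate to < 1%).  The detector adds `offset`, a Gaussian
#' autofluorescence background and Gaussian read noise per pixel; values are
#' clipped to `[0, 65535]` and quantised to integers.  The fraction of
#' saturated pixels is recorded in the `saturation` attribute.
#'
#' An optional signal-proportional variance term (`shot_noise_factor > 0`)
#' adds Gaussian noise with variance `shot_noise_factor * signal`,
#' emulating PMT shot noise; it is off by default and excluded from the
#' moment oracle unless enabled there too.
#'
#' @param field Tibble from [simulate_molecule_field()] (columns `x_um`,
#'   `y_um`, `size`).  Molecules outside the image contribute via their PSF
#'   tails.
#' @param q0 Brightness per protomer at the beam centre (a.u.).
#' @param psf A [psf_model()].
#' @param detector A [detector_model()].
#' @param pixel_size_um Pixel size in µm.
#' @param shape_px `c(nrow, ncol)` image size in pixels.
#' @param seed Integer seed for the noise draws.
#' @param shot_noise_factor Signal-proportional variance coefficient.
#' @return A [confocal_image()].
#' @export
render_image <- function(field, q0 = 205, psf = psf_model(),
                         detector = detector_model(),
                         pixel_size_um = 0.06, shape_px = c(256L, 256L),
                         seed = 1L, shot_noise_factor = 0) {
  stopifnot(inherits(psf, "psf_model"), inherits(detector, "detector_model"))
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be positive.")
  nr <- as.integer(shape_px[1]); nc <- as.integer(shape_px[2])
  set.seed(seed)
  signal <- matrix(0, nr, nc)
  if (nrow(field) > 0) {
    signal <- stamp_molecules(signal,
                              field$x_um / pixel_size_um,
                              field$y_um / pixel_size_um,
                              field$size * q0,
                              psf$w_xy / pixel_size_um)
  }
  n <- nr * nc
  img <- signal + detector$offset +
    rnorm(n, detector$background_mean, detector$background_sd) +
    rnorm(n, 0, detector$read_noise_sd)
  if (shot_noise_factor > 0)
    img <- img + rnorm(n, 0, sqrt(shot_noise_factor * pmax(signal, 0)))
  sat <- mean(img > 65535)
  img <- matrix(round(pmin(65535, pmax(0, img))), nr, nc)
  out <- confocal_image(img, pixel_size_um, detector)
  attr(out, "saturation") <- sat
  out
}

#' Analytic pixel moments of the rendered-image model
#'
#' Closed-form first two moments of the pixel distribution implied by
#' [render_image()], via Campbell's theorem for the Poisson molecule field:
#' \deqn{E[I] = \mathrm{offset} + I_{bg} + \sum_m C_m\, m\, q_0\, A_{PSF}}
#' \deqn{\mathrm{Var}[I] = \sigma_{det}^2 + \sigma_{bg}^2 +
#'   \sum_m C_m\, (m q_0)^2\, \gamma\, A_{PSF}}
#' where \eqn{A_{PSF} = \pi w_{xy}^2 / 2} is the PSF area integral and
#' \eqn{\gamma = 1/2} arises because \eqn{\int \mathrm{PSF}^2 = \gamma
#' A_{PSF}} for the Gaussian beam.  No pixel-area normalisation enters: the
#' expectation of a sum of stamps from a spatial Poisson process is the
#' density times the stamp integral, regardless of the sampling grid.
#' Serves as the simulation-free oracle for all brightness estimators.
#'
#' @inheritParams render_image
#' @param mixture A [species_mixture()].
#' @return A one-row tibble with `expected_mean` and `expected_variance`
#'   (a.u. and a.u.²).
#' @export
closed_form_moments <- function(mixture, psf = psf_model(),
                                detector = detector_model(),
                                pixel_size_um = 0.06,
                                shot_noise_factor = 0) {
  sp <- mixture$species
  a1 <- psf_area(psf$w_xy)
  a2 <- a1 / 2                     # integral of PSF^2 for a Gaussian beam
  sig_mean <- sum(sp$density * sp$size * mixture$q0) * a1
  sig_var <- sum(sp$density * (sp$size * mixture$q0)^2) * a2
  tibble(
    expected_mean = detector_pedestal(detector) + sig_mean,
    expected_variance = detector_noise_var(detector) + sig_var +
      shot_noise_factor * sig_mean)
}

#' High-intensity punctae specification
#'
#' Bright Gaussian blobs mimicking internalised endocytic vesicles, used to
#' exercise the despotting stage.  Purely synthetic contamination.
#'
#' @param count_density Punctae per µm² (>= 0).
#' @param intensity_scale Peak amplitude as a multiple of the image mean.
#' @param radius_um Gaussian radius of the blob in µm.
#' @return An object of class `puncta_spec`.
#' @export
puncta_spec <- function(count_density = 0.02, intensity_scale = 10,
                        radius_um = 0.3) {
  if (any(c(count_density, intensity_scale, radius_um) < 0))
    abort("all puncta parameters must be >= 0.")
  structure(list(count_density = count_density,
                 intensity_scale = intensity_scale, radius_um = radius_um),
            class = "puncta_spec")
}

#' Contaminate an image with high-intensity punctae
#'
#' Adds 2-D Gaussian blobs (`peak * exp(-r^2 / (2 R^2))`) at Poisson-random
#' locations, with peak amplitude `intensity_scale` times the current image
#' mean.  Returns both the contaminated image and the ground-truth mask
#' (pixels receiving at least 10% of a blob peak), for testing spot-removal.
#'
#' @param image A [confocal_image()].
#' @param spec A [puncta_spec()].
#' @param seed Integer seed.
#' @return A list with `image` (contaminated [confocal_image()]) and `mask`
#'   (logical matrix, `TRUE` on puncta pixels).
#' @export
add_punctae <- function(image, spec = puncta_spec(), seed = 1L) {
  stopifnot(inherits(image, "confocal_image"), inherits(spec, "puncta_spec"))
  nr <- nrow(image$data); nc <- ncol(image$data)
  px <- image$pixel_size_um
  area <- nr * nc * px^2
  set.seed(seed)
  n <- rpois(1L, spec$count_density * area)
  mask <- matrix(FALSE, nr, nc)
  if (n == 0 || spec$intensity_scale == 0) {
    if (n > 0 && spec$radius_um > 0) {
      # zero-amplitude blobs still have a (trivially detectable) footprint
      mask <- puncta_mask(nr, nc, runif(n, 0, nc), runif(n, 0, nr),
                          spec$radius_um / px)
    }
    return(list(image = image, mask = mask))
  }
  cx <- runif(n, 0, nc); cy <- runif(n, 0, nr)
  r_px <- spec$radius_um / px
  peak <- spec$intensity_scale * mean(image$data)
  # Gaussian blob exp(-r^2/(2R^2)); stamp kernel uses waist w = 2R
  blob <- stamp_molecules(matrix(0, nr, nc), cx, cy, rep(peak, n),
                          2 * r_px, trunc_waists = 2.5)
  mask <- blob >= 0.1 * peak
  dat <- matrix(round(pmin(65535, image$data + blob)), nr, nc)
  list(image = confocal_image(dat, px, image$detector), mask = mask)
}

puncta_mask <- function(nr, nc, cx, cy, r_px) {
  # pixels within the 10%-of-peak contour radius
  rad <- r_px * sqrt(2 * log(10))
  mask <- matrix(FALSE, nr, nc)
  xs <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  for (k in seq_along(cx))
    mask <- mask | ((xs - cx[k])^2 + (ys - cy[k])^2 <= rad^2)
  mask
}

#' Simulate a monomer calibration series
#'
#' Pure-monomer fields emulating the concentration-calibrated mEGFP monomer
#' solutions used for quantal-brightness calibration.  The default densities
#' span the 12.5--100 protomers/µm² calibration range; densities below the
#' 15 protomers/µm² reliability floor are flagged in their manifest.
#'
#' @param densities Monomer densities in molecules/µm² (> 0).
#' @param q0 Brightness per protomer (a.u.).
#' @param psf A [psf_model()].
#' @param detector A [detector_model()].
#' @param seeds Integer seeds, one per density.
#' @param shape_px Image size `c(nrow, ncol)` in pixels.
#' @param pixel_size_um Pixel size in µm.
#' @param margin_um Simulated border strip around the imaged area (µm), so
#'   edge pixels receive PSF tails from just-outside molecules.
#' @return A list of `list(image, manifest)` pairs; each manifest records
#'   the mixture, detector, PSF, seed, true density and flags, and is
#'   sufficient to re-run the simulation bit-identically.
#' @export
simulate_calibration_series <- function(densities = c(12.5, 20, 50, 100),
                                        q0 = 205, psf = psf_model(),
                                        detector = detector_model(),
                                        seeds = seq_along(densities),
                                        shape_px = c(256L, 256L),
                                        pixel_size_um = 0.06,
                                        margin_um = 1) {
  if (any(densities <= 0)) abort("`densities` must be positive.")
  stopifnot(length(seeds) == length(densities))
  purrr::map2(densities, seeds, function(dens, seed) {
    mx <- species_mixture(1L, dens, q0 = q0)
    fld <- field_with_margin(mx, shape_px, pixel_size_um, margin_um, seed)
    img <- render_image(fld, q0 = q0, psf = psf, detector = detector,
                        pixel_size_um = pixel_size_um, shape_px = shape_px,
                        seed = seed + 10000L)
    manifest <- list(
      mixture = list(sizes = 1L, densities = dens, q0 = q0),
      detector = unclass(detector),
      psf = list(w_xy = psf$w_xy, form = psf$form),
      seed = seed, noise_seed = seed + 10000L,
      pixel_size_um = pixel_size_um, shape_px = c(nrow(img$data), ncol(img$data)),
      true_density = dens,
      n_molecules = nrow(fld),
      total_protomers = sum(fld$size),
      saturation = attr(img, "saturation"),
      flags = if (dens < 15) "below reliable calibration floor" else character(0))
    list(image = img, manifest = manifest)
  })
}
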