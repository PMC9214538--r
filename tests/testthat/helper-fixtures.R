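# shared fixture builders; everything is generated in code at test time

# a rectangular RoI polygon (0-based pixel-corner coordinates)
rect_roi <- function(x0, y0, w, h, name = "roi") {
  tibble::tibble(name = name,
                 vertices = list(cbind(c(x0, x0 + w, x0 + w, x0),
                                       c(y0, y0, y0 + h, y0 + h))))
}

# render a field of a single oligomer size with a PSF-tail margin
sim_pure_image <- function(size, protomer_density, shape_px = c(240L, 240L),
                           seed = 1L, detector = detector_model(),
                           q0 = 205) {
  mx <- species_mixture(size, protomer_density / size, q0 = q0)
  fld <- fifspec:::field_with_margin(mx, shape_px, 0.06, 1, seed)
  render_image(fld, q0 = q0, detector = detector, shape_px = shape_px,
               seed = seed + 5000L)
}

# noiseless detector for deterministic image-formation checks
quiet_detector <- function(offset = 100) {
  detector_model(offset = offset, read_noise_sd = 0,
                 background_mean = 0, background_sd = 0)
}
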