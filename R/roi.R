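#' Rasterize a polygon onto the image grid
#'
#' A pixel belongs to the RoI iff its centre lies inside the polygon.
#' Vertices are in 0-based pixel-corner coordinates, so pixel `(i, j)`
#' (1-based row/column) has centre `(x, y) = (j - 0.5, i - 0.5)`.
#'
#' @param vertices n x 2 matrix of polygon vertices (x, y).
#' @param nrow,ncol Image dimensions in pixels.
#' @return A logical matrix of the image dimensions.
#' @export
rasterize_polygon <- function(vertices, nrow, ncol) {
  validate_polygon(vertices, "<polygon>")
  # restrict the point-in-polygon test to the bounding box
  jr <- max(1L, floor(min(vertices[, 1])) ): min(ncol, ceiling(max(vertices[, 1])))
  ir <- max(1L, floor(min(vertices[, 2])) ): min(nrow, ceiling(max(vertices[, 2])))
  mask <- matrix(FALSE, nrow, ncol)
  if (length(jr) == 0 || length(ir) == 0) return(mask)
  ctrs <- cbind(rep(jr - 0.5, each = length(ir)),
                rep(ir - 0.5, times = length(jr)))
  inside <- mgcv::in.out(rbind(vertices, vertices[1, ]), ctrs)
  mask[ir, jr] <- matrix(inside, length(ir), length(jr))
  mask
}

# Finite-area correlation factor v of the Gaussian-PSF signal field.
#
# The signal contributed by a Poisson field of molecules imaged through a
# Gaussian PSF exp(-2 r^2 / w^2) has spatial autocorrelation
# rho(d) = exp(-d^2 / w^2).  The sample variance over a finite pixel set S
# then underestimates the field variance: E[s^2] = sigma^2 * (1 - v) with
# v = mean over ordered pixel pairs (i, j) in S of rho(|p_i - p_j|).
# Brightness estimators divide the noise-corrected variance by (1 - v).

# separable closed form for an nx x ny pixel rectangle
corr_factor_rect <- function(nx, ny, w_px) {
  v1 <- function(n) {
    d <- seq_len(n - 1)
    (n + 2 * sum((n - d) * exp(-d^2 / w_px^2))) / n^2
  }
  v1(nx) * v1(ny)
}

# general pixel mask: accumulate pair counts by kernel offset
corr_factor_mask <- function(mask, w_px) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2) return(0)
  # crop to bounding box
  ir <- range(idx[, 1]); jr <- range(idx[, 2])
  m <- mask[ir[1]:ir[2], jr[1]:jr[2], drop = FALSE]
  nr <- nrow(m); nc <- ncol(m)
  rad <- ceiling(sqrt(-log(1e-9)) * w_px)  # kernel support
  total <- 0
  for (dy in -rad:rad) for (dx in -rad:rad) {
    k <- exp(-(dx^2 + dy^2) / w_px^2)
    if (k < 1e-9) next
    r1 <- max(1, 1 + dy):min(nr, nr + dy)
    c1 <- max(1, 1 + dx):min(nc, nc + dx)
    if (length(r1) == 0 || length(c1) == 0) next
    pairs <- sum(m[r1, c1, drop = FALSE] & m[r1 - dy, c1 - dx, drop = FALSE])
    total <- total + k * pairs
  }
  total / n^2
}

# correlation factor for a segment/RoI; mask may be a logical matrix or a
# c(nx, ny) rectangle size
corr_factor <- function(mask, psf, pixel_size_um) {
  w_px <- psf$w_xy / pixel_size_um
  if (is.matrix(mask)) {
    # exact separable form when the mask is a full rectangle
    if (all(mask)) return(corr_factor_rect(ncol(mask), nrow(mask), w_px))
    return(corr_factor_mask(mask, w_px))
  }
  corr_factor_rect(mask[1], mask[2], w_px)
}
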