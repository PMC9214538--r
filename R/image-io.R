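#' Confocal image container
#'
#' A 16-bit grayscale confocal frame: an integer matrix of detector counts
#' (a.u.) plus the lateral pixel size in µm and, optionally, the detector
#' calibration it was recorded (or simulated) with.
#'
#' @param data Numeric matrix of pixel values (rows = y, columns = x).
#' @param pixel_size_um Lateral pixel size in µm (the calibration imaging
#'   used 60-nm pixels, i.e. 0.06).
#' @param detector Optional [detector_model()].
#'
#' @return An object of class `confocal_image`.
#' @export
confocal_image <- function(data, pixel_size_um = 0.06, detector = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    abort("`data` must be a numeric matrix.")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    abort("`pixel_size_um` must be a single positive number.")
  if (!is.null(detector) && !inherits(detector, "detector_model"))
    abort("`detector` must be a detector_model or NULL.")
  storage.mode(data) <- "double"
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 detector = detector),
            class = "confocal_image")
}

#' @export
print.confocal_image <- function(x, ...) {
  cat(sprintf("<confocal_image> %d x %d px, pixel %g um, range [%g, %g] a.u.\n",
              nrow(x$data), ncol(x$data), x$pixel_size_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.confocal_image <- function(x) dim(x$data)

#' Read a confocal image from a 16-bit grayscale TIFF
#'
#' Intensities are read as recorded, with no rescaling.  The pixel size is
#' taken from a JSON sidecar (`<path>.json`, as written by [write_image()])
#' or from the `pixel_size_um` argument; images without a pixel size are
#' rejected, as are RGB/multi-channel TIFFs.
#'
#' @param path Path to a single-plane grayscale TIFF (8 or 16 bit).
#' @param pixel_size_um Pixel size in µm; overrides the sidecar.
#' @return A [confocal_image()].
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) != 2L)
    abort(sprintf("'%s' is not a single-channel grayscale image.", basename(path)))
  sidecar <- paste0(path, ".json")
  detector <- NULL
  if (is.null(pixel_size_um) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$detector))
      detector <- do.call(detector_model, as.list(meta$detector))
  }
  if (is.null(pixel_size_um))
    abort(sprintf("no pixel size for '%s': supply `pixel_size_um` or a sidecar.",
                  basename(path)))
  confocal_image(raw, pixel_size_um, detector)
}

#' Write a confocal image as a 16-bit TIFF with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the pixel size and detector
#' calibration so that [read_image()] round-trips bit-exactly.
#'
#' @param image A [confocal_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "confocal_image"))
  dat <- image$data
  if (any(dat < 0 | dat > 65535)) abort("pixel values outside 16-bit range.")
  tiff::writeTIFF(dat / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- list(pixel_size_um = image$pixel_size_um)
  if (!is.null(image$detector))
    meta$detector <- unclass(image$detector)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read region-of-interest polygons from JSON
#'
#' The native annotation format is a JSON array of objects
#' `{"name": ..., "vertices": [[x, y], ...]}` with vertices in 0-based pixel
#' coordinates (pixel-corner frame: pixel `(i, j)` spans `x` in
#' `[j-1, j]`, `y` in `[i-1, i]`).
#'
#' @param path Path to the RoI JSON file.
#' @return A tibble with columns `name` and `vertices` (list of n x 2
#'   matrices).
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0) abort("no RoIs in file.")
  nms <- vapply(raw, function(r) as.character(r$name %||% ""), character(1))
  if (any(nms == "")) abort("every RoI needs a non-empty name.")
  if (anyDuplicated(nms))
    abort(sprintf("duplicate RoI name '%s'.", nms[anyDuplicated(nms)]))
  polys <- lapply(seq_along(raw), function(i) {
    v <- raw[[i]]$vertices
    m <- do.call(rbind, lapply(v, function(p) as.numeric(unlist(p))))
    validate_polygon(m, nms[i])
    m
  })
  tibble(name = nms, vertices = polys)
}

#' Write region-of-interest polygons to JSON
#' @param rois Tibble as returned by [read_rois()], or a named list of
#'   n x 2 vertex matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  if (!is.data.frame(rois))
    rois <- tibble(name = names(rois), vertices = unname(rois))
  out <- purrr::map2(rois$name, rois$vertices, function(nm, v) {
    list(name = nm, vertices = apply(unname(v), 1, as.list, simplify = FALSE))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_polygon <- function(m, name) {
  if (!is.matrix(m) || ncol(m) != 2 || nrow(m) < 3)
    abort(sprintf("RoI '%s': a polygon needs at least 3 x/y vertices.", name))
  if (any(!is.finite(m)))
    abort(sprintf("RoI '%s': non-finite vertex.", name))
  if (polygon_self_intersects(m))
    abort(sprintf("RoI '%s': polygon is self-intersecting.", name))
  invisible(m)
}

# simple O(n^2) check that non-adjacent edges do not cross
polygon_self_intersects <- function(m) {
  n <- nrow(m)
  a <- m
  b <- m[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip edges sharing a vertex
    for (j in js) {
      d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}
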