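#' Analysis configuration
#'
#' Bundles every tunable of the FIF pipeline so that a run is fully
#' reproducible from config + inputs + seed.
#'
#' @param seed Integer seed covering all stochastic steps.
#' @param detector A [detector_model()] (used when images carry none).
#' @param psf A [psf_model()].
#' @param q0 Monomeric brightness (a.u./protomer).
#' @param gamma PSF shape factor.
#' @param bin_edges Spectrogram concentration bin edges (protomers/µm²).
#' @param segment_px Segment side in pixels.
#' @param despot Whether to mask high-intensity punctae before
#'   segmentation.
#' @param despot_k,despot_dilate Despot threshold (MAD multiples) and
#'   dilation radius; see [despot()].
#' @param pool_range Concentration range pooled for condition comparison.
#' @param weighting Fraction readout convention passed to
#'   [fit_oligomer_fractions()]; the pipeline default is `"count"`, the
#'   appropriate readout for spatially intermixed populations (see the
#'   methods vignette).
#' @param n_max Largest fitted oligomer size.
#' @param min_segments Minimum segments per spectrogram bin.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, detector = detector_model(),
                       psf = psf_model(), q0 = 205, gamma = 0.5,
                       bin_edges = seq(15, 65, by = 10), segment_px = 20L,
                       despot = TRUE, despot_k = 5, despot_dilate = 1L,
                       pool_range = c(25, 55),
                       weighting = c("count", "protomer"), n_max = 4L,
                       min_segments = 20L, out_dir = NULL) {
  weighting <- match.arg(weighting)
  structure(list(seed = as.integer(seed), detector = detector, psf = psf,
                 q0 = q0, gamma = gamma, bin_edges = bin_edges,
                 segment_px = as.integer(segment_px), despot = despot,
                 despot_k = despot_k, despot_dilate = despot_dilate,
                 pool_range = pool_range, weighting = weighting,
                 n_max = as.integer(n_max),
                 min_segments = as.integer(min_segments),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full FIF analysis pipeline
#'
#' Executes, per condition and replicate: despotting, RoI segmentation,
#' per-segment Gaussian fits, brightness/concentration estimation,
#' spectrogram construction, multi-Gaussian decomposition into oligomer
#' fractions and pooling over the comparison concentration range; then a
#' one-way ANOVA + Tukey comparison across conditions.  Every discarded
#' segment or bin is logged with a machine-readable reason.  Identical
#' config, inputs and seed give identical outputs.
#'
#' @param conditions Named list (one element per condition label); each
#'   condition is a list of replicates; each replicate is either a
#'   [confocal_image()], a TIFF path, a list of those, or a list with
#'   elements `images` and optional `rois` (tibble or RoI JSON path).
#' @param config A [run_config()].
#' @return An object of class `fif_run`: list with `per_segment`,
#'   `fractions_by_bin`, `pooled` (per replicate), `comparison` (a
#'   `fif_comparison`, or `NULL` when only one condition), and `log`.
#'   With `config$out_dir` set, also writes `per_segment.csv`,
#'   `pooled_fractions.csv`, `comparison.csv`, `run.json` there.
#' @export
run_pipeline <- function(conditions, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    abort("`conditions` must be a named list (condition labels).")
  logs <- list()
  note <- function(...) logs[[length(logs) + 1L]] <<- tibble(...)

  seg_all <- list(); frac_all <- list(); pooled <- list()
  for (cond in names(conditions)) {
    reps <- conditions[[cond]]
    for (r in seq_along(reps)) {
      rep_in <- normalize_replicate(reps[[r]])
      stats <- purrr::map(seq_along(rep_in$images), function(i) {
        img <- rep_in$images[[i]]
        if (is.character(img)) img <- read_image(img)
        mask <- NULL
        if (config$despot) {
          dsp <- despot(img, rep_in$rois, k = config$despot_k,
                        dilate = config$despot_dilate)
          mask <- dsp$mask
          if (any(mask))
            note(condition = cond, replicate = r, stage = "despot",
                 item = sprintf("image_%d", i), reason = "puncta_masked",
                 n = sum(mask))
        }
        st <- segment_stats(img, rep_in$rois, detector = config$detector,
                            psf = config$psf, q0 = config$q0,
                            gamma = config$gamma,
                            segment_px = config$segment_px, mask = mask)
        st$image <- i
        st
      })
      stats <- dplyr::bind_rows(stats)
      bad <- stats[!is.na(stats$reason), ]
      if (nrow(bad) > 0)
        for (rs in unique(bad$reason))
          note(condition = cond, replicate = r, stage = "segment",
               item = rs, reason = rs, n = sum(bad$reason == rs))
      stats$condition <- cond
      stats$replicate <- r
      seg_all[[length(seg_all) + 1L]] <- stats

      spec <- suppressWarnings(
        build_spectrogram(stats, bin_edges = config$bin_edges,
                          min_segments = config$min_segments))
      n_low <- stats$concentration < min(config$bin_edges)
      if (any(n_low, na.rm = TRUE))
        note(condition = cond, replicate = r, stage = "spectrogram",
             item = "below_floor", reason = "concentration_below_floor",
             n = sum(n_low, na.rm = TRUE))
      fr <- fit_oligomer_fractions(spec, monomer_brightness = config$q0,
                                   n_max = config$n_max,
                                   weighting = config$weighting,
                                   min_segments = config$min_segments)
      skipped <- as_tibble(fr)[!fr$fit_ok, ]
      if (nrow(skipped) > 0)
        note(condition = cond, replicate = r, stage = "fractions",
             item = "bins_skipped", reason = "too_few_segments_or_fit_failure",
             n = nrow(skipped))
      fr_tbl <- as_tibble(fr)
      fr_tbl$condition <- cond
      fr_tbl$replicate <- r
      frac_all[[length(frac_all) + 1L]] <- fr_tbl

      pl <- tryCatch(pool_fractions(fr, config$pool_range[1],
                                    config$pool_range[2]),
                     error = function(e) NULL)
      if (is.null(pl)) {
        note(condition = cond, replicate = r, stage = "pool",
             item = "empty_range", reason = "no_bins_in_pool_range", n = 0L)
      } else {
        pl$condition <- cond
        pl$replicate <- r
        pooled[[length(pooled) + 1L]] <- pl
      }
    }
  }
  pooled <- dplyr::bind_rows(pooled)
  comparison <- NULL
  if (length(unique(pooled$condition)) >= 2 &&
      all(table(pooled$condition) >= 2)) {
    comparison <- compare_conditions(pooled)
  }
  out <- structure(
    list(per_segment = dplyr::bind_rows(seg_all),
         fractions_by_bin = dplyr::bind_rows(frac_all),
         pooled = pooled, comparison = comparison,
         log = dplyr::bind_rows(logs), config = config),
    class = "fif_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

#' @export
print.fif_run <- function(x, ...) {
  cat("<fif_run>", nrow(x$per_segment), "segments,",
      nrow(x$pooled), "replicate fraction sets\n")
  if (nrow(x$pooled) > 0) print(x$pooled)
  invisible(x)
}

normalize_replicate <- function(rep_in) {
  if (inherits(rep_in, "confocal_image") || is.character(rep_in))
    rep_in <- list(images = list(rep_in))
  if (is.null(rep_in$images)) rep_in <- list(images = rep_in)
  if (!is.list(rep_in$images)) rep_in$images <- list(rep_in$images)
  if (is.character(rep_in$rois)) rep_in$rois <- read_rois(rep_in$rois)
  rep_in
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seg <- run$per_segment
  write.csv(seg, file.path(dir, "per_segment.csv"), row.names = FALSE)
  write.csv(run$pooled, file.path(dir, "pooled_fractions.csv"),
            row.names = FALSE)
  if (!is.null(run$comparison))
    write.csv(tidy(run$comparison), file.path(dir, "comparison.csv"),
              row.names = FALSE)
  fr <- run$fractions_by_bin
  fr$eps <- NULL
  jsonlite::write_json(
    list(config = run_config_json(run$config),
         fractions_by_bin = fr, log = run$log),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

run_config_json <- function(cfg) {
  c(cfg[c("seed", "q0", "gamma", "bin_edges", "segment_px", "despot",
          "despot_k", "despot_dilate", "pool_range", "weighting", "n_max",
          "min_segments")],
    list(detector = unclass(cfg$detector),
         psf = list(w_xy = cfg$psf$w_xy, form = cfg$psf$form)))
}

#' Simulate a full imaging condition
#'
#' Forward-simulates the images of one experimental condition: per
#' replicate, one field per requested density, each carrying the same
#' ground-truth oligomer mixture.  Used for end-to-end validation and the
#' shipped demo.
#'
#' @param f_monomer,f_dimer,f_oligomer Ground-truth protomer mole
#'   fractions.
#' @param n_replicates Number of replicates (e.g. neuronal preparations).
#' @param densities Total protomer densities of the simulated fields
#'   (protomers/µm²), spanning the analysis range.
#' @param shape_px Field size in pixels.
#' @param seed Base seed; each field derives its own sub-seed.
#' @param q0 Protomer brightness (a.u.).
#' @param psf,detector Imaging model.
#' @param oligo_sizes Sizes representing the oligomer class.
#' @param pixel_size_um Pixel size (µm).
#' @param margin_um Width of the simulated border strip around the imaged
#'   area, so that edge pixels receive proper PSF-tail contributions from
#'   molecules just outside the frame.
#' @return A condition (list of replicates, each a list of
#'   [confocal_image()]s) ready for [run_pipeline()].
#' @export
simulate_condition <- function(f_monomer, f_dimer, f_oligomer,
                               n_replicates = 3, densities = c(30, 40, 50),
                               shape_px = c(360L, 360L), seed = 1L,
                               q0 = 205, psf = psf_model(),
                               detector = detector_model(),
                               oligo_sizes = c(3, 4),
                               pixel_size_um = 0.06, margin_um = 1) {
  purrr::map(seq_len(n_replicates), function(r) {
    purrr::imap(densities, function(dens, i) {
      sub <- seed + 7919L * r + 101L * i
      mx <- mixture_from_fractions(f_monomer, f_dimer, f_oligomer,
                                   total_density = dens,
                                   oligo_sizes = oligo_sizes, q0 = q0)
      fld <- field_with_margin(mx, shape_px, pixel_size_um, margin_um, sub)
      render_image(fld, q0 = q0, psf = psf, detector = detector,
                   pixel_size_um = pixel_size_um, shape_px = shape_px,
                   seed = sub + 1L)
    })
  })
}

# simulate a field extending margin_um beyond the imaged area on all sides
# (coordinates relative to the image origin, so border molecules go negative)
field_with_margin <- function(mixture, shape_px, pixel_size_um, margin_um,
                              seed) {
  fld <- simulate_molecule_field(
    mixture,
    shape_px[2] * pixel_size_um + 2 * margin_um,
    shape_px[1] * pixel_size_um + 2 * margin_um, seed = seed)
  fld$x_um <- fld$x_um - margin_um
  fld$y_um <- fld$y_um - margin_um
  fld
}
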