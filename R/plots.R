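#' Plot a brightness spectrogram
#'
#' Frequency distribution of segment effective brightness per concentration
#' bin (the "wire histogram" view; the stacked arrangement over bins is the
#' volcano graph).  The dashed line marks the monomeric brightness.
#'
#' @param object A `fif_spectrogram`.
#' @param monomer_brightness Reference monomeric brightness (a.u.).
#' @param bin_width Brightness histogram bin width (a.u.).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fif_spectrogram
#' @export
autoplot.fif_spectrogram <- function(object, monomer_brightness = 205,
                                     bin_width = 20, ...) {
  df <- tidyr::unnest(
    dplyr::mutate(as_tibble(object),
                  bin = sprintf("[%g, %g)", .data$bin_low, .data$bin_high)),
    "eps")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eps)) +
    ggplot2::geom_freqpoly(binwidth = bin_width) +
    ggplot2::geom_vline(xintercept = monomer_brightness, linetype = "dashed") +
    ggplot2::facet_wrap(~bin, scales = "free_y") +
    ggplot2::labs(x = expression(epsilon[eff] ~ "(a.u./protomer)"),
                  y = "frequency of occurrence",
                  title = "Brightness spectrogram by protomer concentration bin")
}

#' Plot oligomer fractions by concentration bin
#'
#' @param object A `fif_fractions`.
#' @param ... Unused.
#' @return A ggplot object (stacked bars of monomer/dimer/oligomer mole
#'   fractions per bin).
#' @method autoplot fif_fractions
#' @export
autoplot.fif_fractions <- function(object, ...) {
  df <- tidy(object)
  df$species <- factor(df$species, levels = c("oligomer", "dimer", "monomer"))
  df$bin <- sprintf("[%g, %g)", df$bin_low, df$bin_high)
  ggplot2::ggplot(df[complete.cases(df), ],
                  ggplot2::aes(x = .data$bin, y = .data$fraction,
                               fill = .data$species)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression("protomer concentration (proto." ~ mu * m^-2 * ")"),
                  y = "mole fraction")
}

#' Plot an MEU calibration distribution
#'
#' Histogram of monomeric-equivalent-unit values (0.2-MEU bins) with the
#' monomer/higher-order boundary.
#'
#' @param object A `qb_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qb_calibration
#' @export
autoplot.qb_calibration <- function(object, ...) {
  df <- object$per_roi[!object$per_roi$excluded, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$meu)) +
    ggplot2::geom_histogram(binwidth = 0.2, boundary = 0,
                            colour = "grey30", fill = "grey80") +
    ggplot2::geom_vline(xintercept = object$meu_boundary,
                        linetype = "dashed") +
    ggplot2::labs(x = "MEU", y = "frequency",
                  subtitle = sprintf("QB %.1f +/- %.1f; boundary %.3f",
                                     object$mean_qb, object$sd_qb,
                                     object$meu_boundary))
}

#' Plot pooled fractions per condition
#'
#' @param object A `fif_comparison`.
#' @param ... Unused.
#' @return A ggplot object (mean +/- SD across replicates per species and
#'   condition).
#' @method autoplot fif_comparison
#' @export
autoplot.fif_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$data,
                            cols = dplyr::starts_with("f_"),
                            names_to = "species", names_prefix = "f_",
                            values_to = "fraction")
  summ <- dplyr::summarise(
    dplyr::group_by(df, .data$condition, .data$species),
    mean = mean(.data$fraction), sd = sd(.data$fraction), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$species, y = .data$mean,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mole fraction")
}
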