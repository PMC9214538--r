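#' Tidy a condition comparison
#'
#' @param x A `fif_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return The Tukey pairwise-comparison tibble.
#' @method tidy fif_comparison
#' @export
tidy.fif_comparison <- function(x, ...) x$tukey

#' One-row-per-species ANOVA summary of a condition comparison
#' @inheritParams tidy.fif_comparison
#' @return The per-species ANOVA tibble.
#' @method glance fif_comparison
#' @export
glance.fif_comparison <- function(x, ...) x$anova

#' Tidy a quantal-brightness calibration
#'
#' @param x A `qb_calibration` from [estimate_quantal_brightness()].
#' @param ... Unused.
#' @return The per-RoI tibble (QB, MEU, exclusion flags).
#' @method tidy qb_calibration
#' @export
tidy.qb_calibration <- function(x, ...) x$per_roi

#' One-row summary of a quantal-brightness calibration
#' @inheritParams tidy.qb_calibration
#' @return Tibble with `mean_qb`, `sd_qb`, `meu_boundary`, `n_roi`.
#' @method glance qb_calibration
#' @export
glance.qb_calibration <- function(x, ...) {
  tibble(mean_qb = x$mean_qb, sd_qb = x$sd_qb,
         meu_boundary = x$meu_boundary, n_roi = x$n_roi)
}

#' Tidy an oligomer-fraction fit
#'
#' @param x A `fif_fractions` from [fit_oligomer_fractions()].
#' @param ... Unused.
#' @return A long tibble: one row per bin and species class.
#' @method tidy fif_fractions
#' @export
tidy.fif_fractions <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[, c("bin_low", "bin_high", "n_segments",
                                       "f_monomer", "f_dimer", "f_oligomer")],
                      cols = dplyr::starts_with("f_"),
                      names_to = "species", names_prefix = "f_",
                      values_to = "fraction")
}
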