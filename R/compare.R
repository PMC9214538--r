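#' Compare oligomer fractions across experimental conditions
#'
#' For each species class (monomer, dimer, oligomer), runs a one-way ANOVA
#' of the per-replicate pooled fractions across conditions followed by
#' Tukey's honestly-significant-difference pairwise comparisons.
#' Significance tiers follow the usual convention:
#' `*` p < 0.05, `***` p < 0.001, `****` p < 0.0001 (`ns` otherwise).
#'
#' @param fractions A tibble with columns `condition`, `replicate`,
#'   `f_monomer`, `f_dimer`, `f_oligomer` — one row per replicate (e.g. one
#'   neuronal preparation), as assembled by [run_pipeline()] or manually
#'   from [pool_fractions()] results.
#' @return An object of class `fif_comparison`: list with `anova` (tibble:
#'   species, df_between, df_within, f_statistic, p_value) and `tukey`
#'   (tibble: species, contrast, estimate, conf_low, conf_high, p_adj,
#'   tier).
#' @export
compare_conditions <- function(fractions) {
  need <- c("condition", "replicate", "f_monomer", "f_dimer", "f_oligomer")
  if (!all(need %in% names(fractions)))
    abort(paste("`fractions` needs columns:", paste(need, collapse = ", ")))
  counts <- table(fractions$condition)
  if (length(counts) < 2) abort("need at least 2 conditions.")
  low <- names(counts)[counts < 2]
  if (length(low) > 0)
    abort(sprintf("condition '%s' has fewer than 2 replicates.", low[1]))
  species <- c(monomer = "f_monomer", dimer = "f_dimer",
               oligomer = "f_oligomer")
  res <- purrr::imap(species, function(col, sp) {
    df <- data.frame(y = fractions[[col]],
                     condition = factor(fractions$condition))
    fit <- aov(y ~ condition, data = df)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$condition
    list(
      anova = tibble(species = sp, df_between = an$Df[1],
                     df_within = an$Df[2],
                     f_statistic = an$`F value`[1],
                     p_value = an$`Pr(>F)`[1]),
      tukey = tibble(species = sp, contrast = rownames(tk),
                     estimate = tk[, "diff"], conf_low = tk[, "lwr"],
                     conf_high = tk[, "upr"], p_adj = tk[, "p adj"],
                     tier = significance_tier(tk[, "p adj"])))
  })
  structure(list(anova = dplyr::bind_rows(purrr::map(res, "anova")),
                 tukey = dplyr::bind_rows(purrr::map(res, "tukey")),
                 data = as_tibble(fractions)),
            class = "fif_comparison")
}

significance_tier <- function(p) {
  dplyr::case_when(p < 1e-4 ~ "****", p < 1e-3 ~ "***",
                   p < 0.05 ~ "*", TRUE ~ "ns")
}

#' @export
print.fif_comparison <- function(x, ...) {
  cat("<fif_comparison>", length(unique(x$data$condition)), "conditions,",
      nrow(x$data), "replicate fraction sets\n\nANOVA:\n")
  print(x$anova)
  cat("\nTukey HSD:\n")
  print(x$tukey)
  invisible(x)
}
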