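# fifspec

Quantifying the oligomeric state of fluorophore-tagged membrane proteins —
how much of a receptor population is monomeric, dimeric or higher-order —
from laser-scanning confocal images, by fluorescence fluctuation analysis.
The package is written for quantitative imaging labs studying receptor
quaternary structure (e.g. GPCRs tagged with mEGFP in primary cells), and
implements two complementary estimators plus a full forward simulator used
to validate them:

* **SpIDA quantal-brightness calibration** — per region of interest (RoI),
  the quantal brightness of a monomer standard is estimated from the
  noise-corrected pixel-intensity variance over the corrected mean,

  ```
  QB = (s² − σ²_det − σ²_bg) / (1 − v) / (Ī − offset − I_bg)
  ```

  where `v` is a finite-area correlation correction for the spatially
  correlated Gaussian-PSF signal.  RoI brightness is expressed in
  monomeric equivalent units (MEU = RoI QB / reference QB), with the
  monomer/higher-order boundary at `1 + 1.96·(SD/mean)` of the calibration
  (1.228 for a calibration of 113.5 ± 13.2).  Mean RoI intensity converts
  to surface density via `C = (Ī_c/QB) · γ / ∫∫PSF`.

* **FIF spectrometry** — RoIs are tiled into 400-pixel segments; each
  segment's pixel histogram is fitted with a single Gaussian (Poisson
  maximum likelihood) and converted to an effective brightness
  `ε_eff = (s² − σ²_noise)/(1 − v)/(γ·Ī_c)` (a.u. per protomer) and a
  protomer concentration.  The frequency distribution of `ε_eff` per
  concentration bin (the *brightness spectrogram*) is decomposed by
  non-negative least squares into Gaussian components with centres fixed
  at integer multiples of the monomeric brightness (205 a.u. for mEGFP),
  yielding monomer/dimer/oligomer mole fractions per bin, pooled over
  25–55 protomers/µm² and compared across conditions by one-way ANOVA with
  Tukey's HSD.

* **PSF shape factor** — `γ = ∭PSF² / ∭PSF` over the detected sample
  region, evaluated by adaptive quadrature: 0.5 for a thin layer in the
  focal plane (waist- and pinhole-independent), ≈0.5 for a membrane imaged
  in axial cross-section at a 1-Airy-unit pinhole, `2^(−3/2)` for an
  unbounded 3-D Gaussian.  The axial extent `ω_z` uses the standard
  confocal approximation in wavelength, NA, refractive index and pinhole
  diameter.

* **Forward simulator** — Poisson-distributed oligomer mixtures on a
  planar membrane, Gaussian-PSF image formation at 60-nm pixels, additive
  detector offset/read-noise/autofluorescence background, 16-bit
  quantisation, optional high-intensity punctae (endocytic-vesicle
  mimics) and a matching despot (median + 5·MAD masking) stage.
  `closed_form_moments()` provides the analytic pixel mean/variance the
  simulator must reproduce, so every estimator can be checked against
  ground truth without circularity.

## Worked example

Calibrate quantal brightness on a simulated monomer dilution series, then
analyse a simulated 50/50 monomer/dimer condition end-to-end:

```r
library(fifspec)

ser <- simulate_calibration_series(densities = c(40, 62.5), seeds = 1:2,
                                   shape_px = c(256L, 256L))
cal <- estimate_quantal_brightness(lapply(ser, `[[`, "image"), roi_px = 64L)
cal
#> <qb_calibration> QB = 100.0 +/- 9.6 (mean +/- SD, n = 32 RoIs); MEU boundary 1.188

cond <- simulate_condition(0.5, 0.5, 0, n_replicates = 2,
                           densities = c(30, 40, 50),
                           shape_px = c(360L, 360L), seed = 42)
run  <- run_pipeline(list(mixed = cond), run_config(despot = FALSE))
run$pooled
#> # A tibble: 2 × 7
#>   f_monomer f_dimer f_oligomer n_segments n_bins condition replicate
#>       <dbl>   <dbl>      <dbl>      <int>  <int> <chr>         <int>
#> 1     0.530   0.470    0              845      3 mixed             1
#> 2     0.506   0.492    0.00232        861      3 mixed             2
```

The calibration recovers QB ≈ 100 a.u./molecule — the expected `γ·q0 =
0.5 × 205 = 102.5` for the simulated brightness — and the pipeline
recovers the 50/50 protomer mixture to within a few percent from ~850
segments per replicate.  `autoplot()` methods draw the spectrogram, the
per-bin fraction bars, the MEU histogram and the condition comparison;
`tidy()`/`glance()` return the underlying tibbles.

A thin CLI over the same functions ships in `inst/cli/fifspec.R`
(`simulate`, `gamma`, `spida-calibrate`, `fif-run`, `report`).

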