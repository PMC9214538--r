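---
title: "Brightness-based oligomerization analysis: models, estimators and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brightness-based oligomerization analysis: models, estimators and their limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fifspec)
```

## The measurement problem

A fluorophore-tagged membrane protein imaged on a confocal microscope
produces, per pixel, the summed point-spread-function (PSF) contributions
of all nearby molecules plus detector noise.  Because an n-mer carries n
fluorophores, the *fluctuations* of the signal carry information that the
mean does not: at a fixed total protomer density the mean intensity is
invariant to oligomerization, while the variance grows linearly with
oligomer size.  Every estimator in this package is a ratio built on that
fact.

## Image-formation model and its moments

The simulator places oligomers of size $m$ as a spatial Poisson process
with surface density $C_m$ (oligomers/µm²) and renders each molecule as a
Gaussian beam stamp $m\,q_0 \exp(-2r^2/w_{xy}^2)$ sampled at pixel
centres, with $q_0 = 205$ a.u./protomer and $w_{xy} = 0.2656$ µm — the
package's default calibration values — on a 60-nm pixel grid.  The
detector adds an offset, Gaussian read noise ($\sigma_{det}$) and a
Gaussian autofluorescence background ($I_{bg} \pm \sigma_{bg}$); the frame
is clipped to 16 bits and quantised.  Campbell's theorem then gives the
exact pixel moments implemented in `closed_form_moments()`:

$$E[I] = \mathrm{offset} + I_{bg} + \sum_m C_m\, m\, q_0\, A,\qquad
\mathrm{Var}[I] = \sigma_{det}^2 + \sigma_{bg}^2 +
  \sum_m C_m (m q_0)^2\, \gamma A,$$

with $A = \tfrac12 \pi w_{xy}^2 = 0.111$ µm² the PSF area integral and
$\gamma = \int \mathrm{PSF}^2 / \int \mathrm{PSF} = \tfrac12$ for a thin
layer.  No pixel-area factor appears: the expectation of a Poisson shot
process is density × stamp integral regardless of the sampling grid.
These closed forms are the oracle against which the renderer and all
brightness estimators are tested, which is what makes the round-trip
tests non-circular.

Point sampling of the PSF at pixel centres (rather than integrating over
each pixel) is accurate to well under 1% because the pixel (60 nm) is
much smaller than the waist (265.6 nm).  Photon shot noise is available
as an optional signal-proportional variance term (`shot_noise_factor`)
and is off by default; the moment oracle includes it only when enabled.
Quantisation adds variance ≈ 1/12 a.u.², negligible against the
signal variance (~10⁵ a.u.²) and ignored.

When simulated fields back validation studies, the molecule field extends
1 µm beyond the imaged area on every side (`margin_um`), so edge pixels
receive the PSF tails they would receive inside a larger specimen;
without the margin, edge segments read ~2% dim and brightness ratios
inflate by several percent.

## The finite-area correlation correction

The signal field has spatial autocorrelation
$\rho(d) = \exp(-d^2/w_{xy}^2)$.  A sample variance computed over a
finite pixel set $S$ therefore underestimates the field variance:
$E[s^2] = \sigma^2 (1 - v)$ with $v$ the mean pairwise correlation over
$S$.  For a 20 × 20-pixel segment at the default optics $v \approx 0.12$
— a 12% downward bias that would propagate directly into every
brightness estimate (a pure monomer field would read ~180 a.u. instead of
205).  All variance-based estimators therefore divide the noise-corrected
variance by $(1 - v)$, computed exactly: separably for rectangular pixel
sets, by kernel-offset accumulation for arbitrary polygon masks.  With
this correction the estimators are exact under the image-formation model
above.

## Segment statistics

RoIs (hand-drawn polygons in 0-based pixel-corner coordinates; a pixel
belongs to an RoI iff its centre is inside) are tiled with 20 × 20-pixel
squares anchored at the RoI bounding-box top-left; partial tiles are
discarded.  Each segment's pixel histogram (Freedman–Diaconis bin width,
floored at 1 a.u.) is fitted with a single Gaussian.  The fit is done by
Poisson maximum likelihood rather than unweighted least squares on the
counts: histogram counts are Poisson, and the ML fit tracks the sample
moments to within 5% in >99% of simulated unimodal segments, whereas
unweighted least squares lets the fitted SD wander by up to ~10%.

The fitted Gaussian serves as the segment's quality gate (`fit_ok`:
optimiser convergence, non-collapsed SD).  The brightness and
concentration estimators themselves use the segment's *sample moments*:

$$\varepsilon_{eff} = \frac{(s^2 - \sigma_{det}^2 - \sigma_{bg}^2)/(1-v)}
  {\gamma\,(\bar I - \mathrm{offset} - I_{bg})},\qquad
  C = \frac{\bar I - \mathrm{offset} - I_{bg}}{q_0 A}.$$

This is a deliberate design choice: the pixel distribution of a
shot-noise-limited segment is mildly right-skewed, and a least-squares or
ML Gaussian fit tracks the *mode*, which sits a few percent below the
mean; feeding fitted parameters into the ratio inflates
$\varepsilon_{eff}$ by >10% at typical densities.  The sample moments are
the unbiased summaries, and they coincide with the fitted parameters
exactly in the symmetric case.  Under the simulator model a pure n-mer
field gives $\varepsilon_{eff} \to n q_0$ and $C$ equals the protomer
density irrespective of composition (composition invariance is one of
the acceptance checks).

The same ratio estimator applied to large calibration RoIs is the
quantal-brightness (QB) calibration; an RoI is excluded when its
corrected mean fails to clear three standard errors of a signal-free
RoI, which makes pure-noise inputs fail deterministically rather than by
chance.  MEU values (QB / reference QB) from a monomer standard are
Gaussian — checked with the D'Agostino–Pearson omnibus test (implemented
in-package following D'Agostino, Belanger & D'Agostino 1990, with the
signed cube root in the kurtosis branch, and verified against an
independent implementation) and Shapiro–Wilk — and the
monomer/higher-order boundary is $1 + 1.96\,(\mathrm{SD}/\mathrm{mean})$
rounded to three decimals: 1.228 for a 113.5 ± 13.2 calibration, within
sub-rounding ambiguity of the conventional 1.227.  Classification at the
boundary is inclusive (a value on the boundary is still consistent with
the monomer distribution's 95% coverage).

## Spectrograms and their decomposition

Segments are binned by protomer concentration (default edges 15, 25, …,
65 protomers/µm², half-open `[low, high)`, upper-bin assignment at edges;
segments below 15 protomers/µm² are excluded because the monomer
calibration is unreliable there, and bins with < 20 segments are
flagged).  Each bin's $\varepsilon_{eff}$ histogram is fitted by
non-negative least squares with Gaussians whose centres are fixed at
$n\,\varepsilon_1$, $n = 1..4$, widths $\sigma_n = \sigma_1\sqrt n$ (the
variance of a sum of $n$ independent protomer signals), and the monomer
width $\sigma_1$ profiled over a grid (0.1–0.8 × $\varepsilon_1$ in
steps of 0.025); the inner amplitude problem is solved exactly by NNLS,
which makes the fit deterministic with no starting-point sensitivity.
Oligomer sizes ≥ 3 are pooled into a single class.  Fractions from bins
inside 25–55 protomers/µm² are pooled by segment-count weighting, and
conditions are compared per species class by one-way ANOVA with Tukey's
HSD (significance tiers 0.05 / 0.001 / 0.0001).

### What the fitted areas mean — and when they cannot mean it

Two readout conventions are provided because they answer different
questions about different data:

* If each segment is dominated by a **single** species (spatially
  segregated populations — the classic spectrogram interpretation), the
  fitted areas $A_n$ estimate *entity* fractions, and protomer mole
  fractions are the size-weighted areas $n A_n / \sum n A_n$
  (`weighting = "protomer"`, the default of
  `fit_oligomer_fractions()`).

* If species are **spatially well mixed** at the segment scale — which
  is exactly what the simulator's uniform i.i.d. placement produces —
  every segment's brightness concentrates at the protomer-weighted mean
  of its local contents,
  $\varepsilon_{eff} \to q_0 \sum_m f_m m$ with $f_m$ the protomer
  fractions.  The spectrogram is then *unimodal for any mixture*, and
  matching its first moment forces the fit's count-weighted mean to equal
  that protomer-weighted mean; the areas themselves are therefore the
  protomer-fraction estimates and size re-weighting would double-count
  (`weighting = "count"`, the default of the end-to-end pipeline).

This has a hard corollary that users should understand before trusting
three-class decompositions.  For well-mixed fields the data contain
essentially one identifiable number per bin — the mean oligomer size —
plus weak shape information, because the per-segment estimation noise
(~35% relative SD: a 400-pixel segment holds only ≈ 6–25 independent
beam areas) dwarfs the composition-driven broadening.  Compositions
supported on at most two adjacent sizes (pure monomer; a
monomer/dimer mixture) are recovered accurately — simulated recovery is
within a few percent — but a three-class composition such as 15% / 40% /
45% monomer/dimer/oligomer is *not identifiable* from a well-mixed
field: the fit returns the composition with the correct mean size
concentrated on the bracketing components.  The corresponding
end-to-end acceptance check is left failing, deliberately, as a
statement of this limit rather than being weakened.  Real membranes
with microdomain segregation are closer to the quasi-pure regime, where
the protomer-weighted readout applies; synthetic pure-species
spectrograms confirm that regime recovers three-class compositions
within ±0.10.

## Despotting

High-intensity punctae (internalised vesicles) are masked before
segmentation: a pixel is flagged when it exceeds its RoI's median +
5 × MAD (MAD scaled consistent with the SD), and the flagged set is
dilated by 1 pixel.  Masked pixels are excluded — any tile touching the
mask is dropped — not inpainted, so no synthetic values enter the
statistics.  Against the simulator's puncta model (Poisson-placed
Gaussian blobs, default 0.02/µm², 10× the image mean, 0.3-µm radius;
ground-truth mask at the 10%-of-peak contour) the defaults mask > 80% of
puncta pixels with well under 5% false positives, and the recovered
monomer fraction of a contaminated monomer field stays within 0.10 of
the clean image (in practice the shift is far smaller).

## Shape-factor geometry

`gamma_factor()` evaluates $\int \mathrm{PSF}^2 / \int \mathrm{PSF}$ by
adaptive quadrature on a domain truncated at 6 waists (truncation error
< 10⁻¹⁵ relative).  The thin-layer Gaussian value 0.5 is
waist-invariant (the scale cancels in the ratio) and pinhole-invariant.
For a membrane parallel to the optical axis the detected region is
approximated as a slab bounded laterally by the pinhole aperture
(±PH/2 per lateral axis) and axially by the beam extent (±ω_z/2), with

$$\omega_z = \sqrt{\left[\frac{0.88\,\lambda_{Ex}}{n - \sqrt{n^2 -
NA^2}}\right]^2 + \left[\frac{\sqrt 2\, n\, PH}{NA}\right]^2},$$

the standard confocal axial approximation (the typeset groupings of this
expression vary between sources; this reading — division by the
diffraction term, √2 scaling of the geometric term — is the standard
one and is monotone in PH and λ as it must be).  At a 1-Airy-unit
pinhole (1 AU = 1.22 λ_em/NA with λ_em = 0.555 µm, the centre of the
505–605 nm detection band) and oil-immersion optics (n = 1.518,
NA = 1.4, λ_Ex = 0.488 µm) this slab gives γ ≈ 0.49, supporting the
use of a single γ = 0.5 for all membrane orientations; the agreement is
approximate (the package reports the quadrature value, not 0.5).

## Simulated study conditions and problem sizes

The validation studies use, as their standard conditions: detector
offset 0 (the calibration acquisition's offset setting), read-noise SD
20 a.u., background 50 ± 15 a.u. (plausible autofluorescence magnitudes;
the source calibrations quantify but do not publish theirs); monomer
calibration at 40 and 62.5 molecules/µm² (the two-solution design, within
the 20–100 calibration range) with 16 RoIs of 128 × 128 pixels per
concentration; mixture fields of 360 × 360 pixels at 30, 40 and
50 protomers/µm², giving ≈ 970 segments per replicate across the three
pooled concentration bins; fraction-recovery runs use 10 seeds per
composition.  These sizes put Monte-Carlo error comfortably below the
tolerances being tested while keeping the full suite in the
tens-of-minutes range on a single core.

## What the simulator does not emulate

Uniform planar fields only: no neuronal morphology, no membrane folding
or curvature, no microdomain clustering (hence the identifiability limit
above), no photobleaching, diffusion or z-extent, and Gaussian rather
than gain-scaled PMT noise.  Passing tests demonstrate estimator
correctness under this model — they do not certify accuracy on tissue
images, where RoI selection, despotting aggressiveness and γ drift from
membrane geometry (e.g. after heavy internalisation, which flattens the
effective illumination distribution and can push apparent brightness
below the monomer line) all contribute systematic effects with no
in-package correction.
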