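---
title: "Methods: a Barents Sea bio-optical model for glider and satellite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Barents Sea bio-optical model for glider and satellite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baroptics)
```

## The problem

Gliders on Arctic shelf seas carry a CTD and an optical triplet sensor —
chlorophyll fluorescence, CDOM fluorescence and backscattering at a single
wavelength (700 nm). None of these is a bulk optical property, yet bulk
spectral IOPs (absorption $a$, scattering $b$, backscattering $b_b$) are
what radiative-transfer models and ocean-colour satellites work with. This
package implements a regional bio-optical model that bridges the gap: every
partial IOP is driven by one of two "currency" variables that the glider
measures or that can be derived from its payload — chlorophyll $a$
concentration (Chl) as a proxy for phytoplankton and covarying detrital
material, and salinity (Sal) as a proxy for the freshwater-borne CDOM load.

## Model structure and assumptions

$$a(\lambda) = a_w(\lambda) + a_{CDOM}(\lambda,\mathrm{Sal}) +
  a_{ph}(\lambda,\mathrm{Chl}) + a_{NAP}(\lambda,\mathrm{Chl})$$
$$b(\lambda) = b_w(\lambda) + b_p(\lambda,\mathrm{Chl}), \qquad
  b_b(\lambda) = b_{bw}(\lambda) + b_{bp}(\lambda,\mathrm{Chl})$$

The key assumptions, and where they will break:

* **Particles covary with Chl.** All particulate terms are power laws in
  Chl. Mineral-dominated waters (glacial runoff, resuspension) violate this.
* **CDOM tracks salinity linearly**, $a_{CDOM}(440) = -0.012\,\mathrm{Sal} +
  0.464$ m$^{-1}$, supported only for Sal in [27, 35] PSU. Outside that
  window the model substitutes a constant $a_{CDOM}(440) = 0.04$ m$^{-1}$
  (with a warning); `raw = TRUE` evaluates the regression as written and
  clamps negative values, which exist for Sal $> 38.67$.
* **Spectral shapes are fixed exponentials** for CDOM ($-0.0168$ nm$^{-1}$,
  a regional median; other Arctic waters show $\approx -0.019$) and NAP
  ($-0.011$ nm$^{-1}$).
* The scattering/backscattering tables were fitted on **spring** data and
  are biased toward bloom conditions; winter performance is poorer.
* No inelastic processes: chlorophyll fluorescence emission near 680 nm is
  absent from the forward model, so a red reflectance peak seen by a
  satellite will not be reproduced.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| hybrid switch | 2 | mg m$^{-3}$ | fluorescence trusted below, backscattering above; regional, would need re-tuning elsewhere |
| CDOM validity | [27, 35] | PSU | support of the salinity regression |
| CDOM fallback | 0.04 | m$^{-1}$ | mid-range of observed regional $a_{CDOM}(440)$ |
| grid spacing | 2 × 5 | km × m | native transect resolution |
| Barnes radii | 10 × 10 | km × m | first-pass influence scales |
| Barnes passes, $\gamma$ | 2, 0.3 | — | second pass at 3 km × 3 m restores detail |
| despike window, threshold | 7, 5 | samples, MAD | Hampel filter scales |
| band tolerance | 10 | nm | "closest band, no interpolation" matching |

The switch at 2 mg m$^{-3}$ is **hard**: the estimate jumps where
fluorescence crosses the threshold. A blended estimator would hide the
sensor disagreement that the discontinuity makes visible, so blending was
deliberately not implemented.

## Pinned coefficient tables

The model's own constants are printed in code and shipped as CSVs under
`inst/extdata/`. Two baseline inputs are cited to the literature rather than
printed, and had to be pinned here:

* **Pure-water absorption**: a Pope & Fry (1997)-type integrating-cavity
  table, transcribed at 10 nm resolution, linearly interpolated. Linear
  interpolation cannot overshoot below zero on a positive table, which is
  why no higher-order scheme is used.
* **Pure-seawater scattering**: the classical molecular
  $\lambda^{-4.32}$ power law anchored at $b_w(500) = 0.00222$ m$^{-1}$ for
  pure water, with the published $\approx$30% linear salinity enhancement at
  oceanic salinity, and $b_{bw} = b_w/2$ (symmetric molecular phase
  function). Temperature is accepted by the API but not applied: its
  published effect on $b_w$ is below 1% across polar temperatures, far
  beneath the model's other uncertainties, and a full thermodynamic
  treatment would add complexity without accuracy the rest of the chain can
  use.
* **Phytoplankton absorption coefficients** $A_{ph}, B_{ph}$: the cited
  source table is not redistributable here, so the shipped file
  (`aph_coefficients_synthetic.csv`, marked *synthetic*) anchors at the
  widely cited 440 nm relation $a_{ph}(440) = 0.0654\,\mathrm{Chl}^{0.728}$
  and follows a typical chlorophyll-specific spectral shape elsewhere
  (blue maximum, green trough, secondary red peak at 676 nm). Conclusions
  that depend on the precise $a_{ph}$ spectrum away from 440 nm should not
  lean on this table.

Backscattering at 412 nm is **refused, not extrapolated** — the source
channel was excluded for data-quality reasons — so nine-wavelength bundles
carry `NA` there and reflectance is computed on the remaining eight bands.

## The glider pipeline

1. **Despiking** is a Hampel filter: deviation from a 7-sample rolling
   median, thresholded at 5 local MADs. Two non-obvious choices: the MAD is
   estimated over a wider window ($4\times7+3 = 31$ samples) because a
   7-sample MAD is so noisy that it flags ordinary noise in quiet deep
   water; and the flag-and-replace step is iterated to a fixed point, which
   makes the filter idempotent by construction. A tiny relative floor on
   the MAD keeps constant series from flagging round-off.
2. **Profile splitting** detects depth reversals exceeding a 5 m
   hysteresis, so metre-scale jitter does not fragment profiles. Records
   between the true turning point and the detection point stay with the
   preceding profile; every record belongs to exactly one profile.
3. **Hybrid Chl** as above; the backscattering inversion
   $(b_{bp}(700)/A_{bb}(700))^{1/B_{bb}(700)}$ is an exact left inverse of
   the forward law, verified to $10^{-10}$ relative error.
4. **Barnes gridding**: Gaussian successive correction onto cell centres at
   spacing multiples (origin at the first record; along-track distance is
   accumulated great-circle distance). Pass $p$ uses radii scaled by
   $\gamma^{p-1}$; residuals are taken against a bilinear interpolation of
   the running analysis. Cells farther than 3 first-pass radii (scaled
   distance) from every observation are `NA`, never zero. Reachability is
   judged at first-pass scales only, so later passes refine but never
   extend coverage.
5. **Reflectance**: the 2 m surface-average criterion cannot be met
   literally on a 5 m grid; the surface row (cell centre 0 m, i.e. the
   0–5 m bin) is used, and finer vertical grids are honoured when supplied.

## The synthetic world

The generator emulates the one structure the analysis depends on: a
south-to-north transect along 30°E crossing the polar front at 75.8°N, with
a logistic temperature/salinity drop (5→0.5 °C, 35→34.4 PSU over ~0.15°
latitude — a sharp shelf front) and a surface-intensified bloom north of
the front (background 0.3, peak 8 mg m$^{-3}$, e-folding depth 50 m,
spanning the observed spring range). Sensors apply 3% multiplicative
lognormal noise (optical signals are positive and heteroscedastic), 1%
spike probability with positive excursions of 10–100 MAD, and an optional
daytime quenching factor multiplying fluorescence in the top 20 m —
reproducing the quenching signature (backscatter-Chl exceeding
fluorescence-Chl in surface blooms) without modelling photophysiology.

What a green test does **not** establish: the generator's fields are smooth
logistics/exponentials sampled by an idealized sawtooth, with no advection,
tides, internal waves, sensor drift or bio-fouling. Closure of the pipeline
against truth (relative RMS < 5% in reflectance) certifies the numerical
chain, not the realism of the bio-optical relationships themselves — those
rest on the pinned coefficient tables.

The satellite-ensemble generator draws whole model columns and applies 15%
lognormal band noise. Note the lognormal mean bias: the ensemble mean
converges to $e^{\sigma^2/2} \approx 1.011$ times the noise-free spectrum,
so the band-averaged mean-error metric settles near 1–3% at large $n$, not
at the noise level.

## Numerical choices

* Additivity of bundles is exact summation; tests tolerate $10^{-12}$.
* Coefficient pairs $(A, B)$ are interpolated linearly and independently in
  wavelength between table rows; no extrapolation outside the span.
* The mean-error metric is the band-average of
  $|\bar{R}_{glider} - \bar{R}_{sat}|/\bar{R}_{sat}$ in percent — a
  distribution-mean comparison, chosen because cloud-forced temporal
  averaging makes pixel-to-profile pairing meaningless. Outliers use the
  1.5×IQR boxplot rule.
* All generator randomness flows from a single integer seed, applied in an
  isolated RNG scope that restores the caller's `.Random.seed`.

## Known limitations

Winter (low-signal) conditions strain both the scattering tables and the
fluorescence channel; the CDOM fallback is untested against data by
construction; the hybrid threshold is regional; and reflectance omits
Raman scattering and bidirectional effects, which bias comparisons at the
low solar elevations typical of high latitudes.
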