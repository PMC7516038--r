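---
title: "canopyflux: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{canopyflux: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyflux)
```

## What the package computes

Crop growth is the product of three quantities that this package measures
separately for a canopy enclosed in a steady-state gas-exchange chamber:
how many of the incident photons the canopy absorbs (*photon capture*), how
many moles of CO₂ it fixes in gross photosynthesis per mole of absorbed
photons (*canopy quantum yield*), and what fraction of that fixed carbon it
retains as biomass rather than respiring (*carbon use efficiency*, CUE).
Separating the three turns a biomass difference between light treatments
into a mechanistic statement: a treatment can grow more because it captures
more photons, because it uses them more efficiently, or because it respires
less.

The package covers the full chain for multi-chamber LED experiments —
typically a red/blue or white background with or without a far-red
(700–750 nm) fraction substituting for 400–700 nm photons at constant total
flux — and pairs it with a generator of complete synthetic experiments with
known ground truth.

## Gas exchange

A single differential infra-red gas analyzer is shared between chambers by a
multiplexer: each chamber is sampled for `sample_s` seconds (default 30),
then the tubing is purged for `purge_s` seconds (default 40) before the next
chamber. With four chambers each one is revisited every 280 s.
`demultiplex_stream()` discards purge seconds, and collapses each visit to
one record after dropping the first `window_discard_s` seconds (default
10 s) of the sampling window as equilibration. The source never specifies a
within-window reduction rule; discard-then-average is the obvious robust
choice and its length is a user option.

Net flux per ground area is `P_net = flow × ΔCO₂ / A` (µmol m⁻² s⁻¹), with
the CO₂ differential stored *uptake-positive* so photosynthesis is positive
and dark respiration negative. No water-vapour dilution correction is
applied because the analysis assumes the sampled streams are fully dried
upstream of the analyzer; a standard dilution correction can be layered on
by transforming the stream before demultiplexing.

Daily means are taken over the light and dark periods separately, with day
boundaries at the lights-on event (not midnight). Two exclusion windows
guard the means against non-steady-state samples: `transition_exclusion_min`
minutes (default 10) after each light/dark switch, and `pre_guard_s` seconds
(default 70, one multiplexer slot) before each switch so that a collapsed
averaging window straddling the switch cannot leak across periods. A day is
flagged complete when at least 80% of the expected samples are present in
both periods; a day with one empty period is an error rather than a silent
half-day.

The daily metrics follow the standard canopy carbon bookkeeping:
`P_gross = (P_net,light + |R_dark|) × 14 h × 0.17 m² × 30 g mol⁻¹`,
`DCG = (P_net,light × 14 − |R_dark| × 10) × 0.17 × 30`, `CUE = DCG/P_gross`.
The constants are all parameters of `carbon_conversion()`: photoperiod and
dark period must sum to 24 h, the chamber ground area defaults to 0.17 m²,
and 30 g dry mass per mole of CO₂ corresponds to a tissue carbon fraction of
0.4 g g⁻¹ — an assumption that is the dominant uncertainty when predicting
harvest mass from cumulative DCG, since real carbon fractions vary by a few
percent with tissue composition. The identity
`P_gross − DCG = |R_dark| × 24 h × A × c` holds algebraically and is
enforced by the property tests. Equal respiration in light and dark is
assumed throughout; this is the standard assumption in canopy work and the
package makes no attempt to model light inhibition of respiration.

## Spectra

Spectra are photon flux densities on a strictly increasing wavelength grid
(default 380–780 nm at 1 nm). All integrals are trapezoidal on the native
grid with linear interpolation at band edges, so the conventional bands —
blue [400,500), green [500,600), red [600,700), far-red [700,750] — tile
the 400–750 nm range exactly and their fractions sum to one by
construction. Absorptance spectra and photoconversion coefficient tables on
different grids are linearly interpolated onto the spectrum grid with
end-value extension.

Phytochrome photoequilibrium (PPE) is the flux-weighted ratio
`∫Nσ_r / ∫N(σ_r+σ_fr)`. The package ships a *synthetic* coefficient table
(`inst/extdata/phytochrome_coefficients_synthetic.csv`) built from smooth
Gaussian absorption bands for the Pr and Pfr forms, scaled so narrow-band
red/blue sources land near the photoequilibria published coefficient sets
give for such sources (≈0.88 for a 663 nm-dominated spectrum). It is a
stand-in with the right shape and ordering, not a published dataset; users
comparing PPE values across papers should load their preferred table with
`read_coefficients_csv()`. PPE estimated from incident spectra ignores
chlorophyll screening inside the leaf, a known limitation of the method
itself.

## Photon capture

Ground cover is the green-pixel fraction of a top-down photograph. The
default classifier is deliberately simple — a pixel is plant if
`G > R`, `G > B`, and `G > 0.15` of full scale — because the reference
work delegates this step to an external script whose exact rule is not
reproducible; the classifier is a swappable function argument, and on the
package's synthetic images it is exact by construction.

Total canopy leaf area is only measured at harvest. For earlier days the
package follows the projected-area logic: while leaves do not yet overlap,
projected area (cover × chamber area) *is* total area; once they overlap,
total area is interpolated by an exponential `A(t) = A₀e^{rt}` fitted by
ordinary least squares in log space to the young-canopy projected areas
plus the harvest total. Days more recent than `overlap_window_d` (default 7)
before harvest are treated as potentially overlapping and excluded from the
fit's young-canopy set. The fitted curve is capped at the harvest total — an
unconstrained exponential necessarily overshoots a decelerating canopy near
harvest, and the cap anchors the estimate at the one day where total area is
actually measured. Leaf layers are `max(1, total/projected)`; the
Beer–Lambert correction `1 − e^{−kL}` with `k = −ln(1 − a)` (single-layer
spectrum-weighted absorption `a`, computed per treatment from that
treatment's spectrum and leaf absorptance) then gives the absorbed fraction
within the covered area, and capture is cover times that fraction. At
`L = 1` the chain reduces exactly to cover × single-leaf absorption, and
the extinction/absorption pair round-trips to machine precision.

## Quantum yield

`P_gross` in g d⁻¹ is converted to mol CO₂ per mol incident photons by
dividing by `c`, the chamber area, and the daily light integral; dividing
further by capture gives quantum yield per absorbed photon. The chamber
area cancels between the daily metrics (×A) and this conversion (÷A), so
the reported quantum yield does not depend on the area constant — a
property the tests check explicitly.

Per-treatment aggregates exclude the first `qy_exclude_days` (default 7)
days: seedling canopies have the least reliable capture estimates (a
±0.005 cover error is a large relative error at 3% cover), and the same
days are excluded from the mature-CUE average by construction (`cue_window_d`,
default 6 final days). The "common slope" question — does gross
photosynthesis rise with capture at the same rate in all treatments? — is
answered descriptively by `regress_on_capture()`: per-treatment OLS slopes,
a pooled slope, and the maximum pairwise relative slope difference. No
significance machinery is attached because the underlying comparison
procedure in the reference work is unstated; the diagnostic is meant to be
read alongside its r² values.

## The synthetic-experiment generator

The generator's defaults *are* the study conditions the package is
validated under, chosen once from the reference experiment's stated
configuration:

* **Spectra** — four treatments (RB 350, RB 300 + FR 50, white 350,
  white 300 + FR 50), each 350 µmol m⁻² s⁻¹ over 400–750 nm with 31.5%
  blue; far-red treatments substitute 50 µmol (1/7 of total). Gaussian
  components (443/663 nm red-blue, 450 nm blue + broad 567 nm phosphor for
  white, 730 nm far-red) are weight-calibrated by iterative proportional
  fitting to the target band fractions, then rescaled so the 400–750
  integral is exact. The two phosphor widths (61.1 and 63.8 nm) were solved
  so the white green:red target 45.2:23.3 is exactly feasible.
* **Leaf absorptance** — two smooth profiles (plateau, green dip, red-edge
  falloff). Their parameters were fitted once so the spectrum-weighted
  single-layer absorptions under the four default spectra reproduce the
  reference scalars 0.927/0.798/0.838/0.686; the curve *shapes* are
  plausible but not traced from measured data.
* **Growth** — logistic total leaf area (`A₀ = 0.004 m²`, `r = 0.304 d⁻¹`,
  saturation 0.55 m²), whose early phase is exponential, consistent with
  the exponential interpolation the analysis itself assumes. The far-red
  expansion multiplier 1.225 on `r` reproduces the reference ~1.43-fold
  harvest leaf-area contrast, and the default 18-day run ends near canopy
  closure with ~1.8 (control) to ~2.6 (far-red) leaf layers. Projected area
  equals total area until cover 0.5, then saturates towards the chamber
  area with a C¹-continuous exponential approach.
* **Physiology** — true quantum yield 0.057 mol mol⁻¹ (spectrally flat
  across treatments, which is the hypothesis the pipeline should be able to
  confirm or refute; a per-treatment multiplier exists to inject
  departures), mature CUE 0.61 ramping from 0.4 over the first 10 days to
  emulate the seedling rise, i.i.d. Gaussian noise of SD 0.5 µmol mol⁻¹ on
  the per-second CO₂ differential (no instrument figure is published; 0.5
  is a plausible differential-IRGA short-term noise), and flow rising
  linearly 11→37 mmol s⁻¹ from seedling to harvest. Respiration is derived
  from the CUE target as `R = t_light·P_gross_rate·(1−CUE)/24`, which makes
  the daily bookkeeping close exactly: cumulative biomass equals initial
  mass plus ΣDCG, so mass-balance closure is 100% by construction on
  noiseless data.
* **Images** — four elliptical rosettes over a soil background, scaled by
  binary search until the realized green fraction is within 0.003 of the
  requested cover (the realized value is recorded in the truth table). The
  images are classifier-exact, not photorealistic.

What passing recovery tests on these data shows is that the *pipeline
arithmetic and estimation chain* are correct under realistic magnitudes and
noise; it does not validate the green-pixel classifier on real photographs,
the absorptance profiles against real leaves, or the equal-respiration and
carbon-fraction assumptions.

## Numerical choices and degenerate inputs

* Trapezoidal quadrature on a 1 nm grid keeps band-integral errors of
  LED-width Gaussians below 10⁻⁴ relative (checked against a 0.01 nm
  oracle).
* The IPF spectrum calibration converges to ~10⁻⁴ absolute in the pinned
  band fractions (limited by the phosphor-width root's precision) and
  errors out if a target is further than 2×10⁻³ after fitting —
  an order of magnitude inside the ±0.3 percentage-point contract.
* Zero-flux spectra, zero denominators (PPE, CUE, capture = 0), empty
  ROIs, non-positive areas and flows, and days with an empty light or dark
  period all raise immediate errors rather than propagating NaN.
* `fit_exponential_growth()` requires ≥ 2 points and positive areas;
  with exactly two it is the exact interpolating exponential.
* Ties in the green classifier (`G == R`) count as background; the
  threshold is strict.
* Seeds: every stochastic component (stream noise, image geometry, growth
  jitter) is driven by one integer seed; equal seeds give byte-identical
  streams and images.

## Problem sizes

The test suite runs full 18-day two-treatment experiments (1.5 million
stream records) for the recovery and mass-balance checks and shorter runs
elsewhere; the acceptance script runs three seeded 18-day four-treatment
experiments. These sizes match the reference experiment's duration and
keep a complete run in tens of seconds on one core.

## Known limitations

* No radiative transfer: horizontal-leaf Beer–Lambert with a single
  per-treatment `k`, no leaf-angle distribution, no side lighting (the
  reference chambers used reflective walls to suppress it).
* PPE from incident spectra with a synthetic coefficient table; no
  chlorophyll-screening correction.
* No sub-daily event analysis (e.g. the transient assimilation drop when
  far-red LEDs switch off); the pipeline works at daily resolution.
* Respiration equals dark respiration in the light; carbon fraction fixed
  at 0.4 g g⁻¹.
* ANOVA-style treatment mean separation is out of scope; the package stops
  at per-treatment summaries and the descriptive common-slope diagnostic.
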