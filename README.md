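# canopyflux

Tools for decomposing whole-canopy growth, as measured in steady-state
gas-exchange chambers, into its three mechanistic components:

1. **canopy photon capture** — the fraction of incident photons (400–750 nm)
   the canopy absorbs,
2. **canopy quantum yield** — moles of CO₂ fixed in gross photosynthesis per
   mole of absorbed photons, and
3. **carbon use efficiency (CUE)** — the fraction of gross carbon fixation
   retained as biomass.

It is aimed at plant physiologists and controlled-environment researchers
who run multi-chamber canopy CO₂-exchange systems under LED light
treatments (for example red/blue or white backgrounds with or without
far-red substitution) and want the complete analysis chain — from the raw
multiplexed infra-red gas analyzer (IRGA) stream and daily top-down canopy
photographs to per-treatment quantum-yield and CUE summaries — in one
scriptable, testable package.

## The model

Mean light-period net assimilation `P_net,light` and dark respiration
`R_dark` (mol CO₂ m⁻² h⁻¹, respiration negative) are averaged per day from
the demultiplexed chamber flux series and converted to daily canopy carbon
metrics in grams of dry mass:

    P_gross = (P_net,light + |R_dark|) × t_light × A × c
    DCG     = (P_net,light × t_light − |R_dark| × t_dark) × A × c
    CUE     = DCG / P_gross

with photoperiod `t_light` (default 14 h), dark period `t_dark` (10 h),
chamber ground area `A` (0.17 m²), and `c` = 30 g dry mass per mol CO₂
(a tissue carbon fraction of 0.4 g g⁻¹). Respiration in the light is assumed
equal to dark respiration.

Canopy photon capture is estimated per day as

    capture = cover × (1 − e^(−k·L))

where `cover` is the green-pixel ground-cover fraction from a top-down
photograph, `L` is the number of overlapping leaf layers (interpolated total
leaf area over projected area, ≥ 1), and the Beer–Lambert extinction
coefficient `k = −ln(1 − a)` is anchored at the spectrum-weighted
single-layer leaf photon absorption `a` of the treatment. Canopy quantum
yield then follows as

    QY = (P_gross / c / A / DLI) / capture        [mol CO₂ / mol photons]

with `DLI` the daily light integral (mol m⁻² d⁻¹, 17.64 for
350 µmol m⁻² s⁻¹ over 14 h).

A synthetic-experiment generator (`simulate_experiment()`) produces all four
input streams — treatment spectra, canopy growth and images, the multiplexed
IRGA stream, and harvest data — from known ground truth, so the entire
pipeline can be exercised and validated without instruments.

## Worked example

Simulate a full four-treatment, 18-day experiment and run the complete
analysis:

```r
library(canopyflux)

sim <- simulate_experiment(days = 18, seed = 42)
res <- analyze_simulation(sim)
for (tr in res$report) {
  h <- tr$harvest
  cat(sprintf("%-18s QY %.4f  CUE %.3f  cover %.2f  capture %.3f  mass %% %.1f\n",
      tr$treatment, h$mean_quantum_yield, h$mean_cue_mature,
      h$final_cover, h$final_capture, h$predicted_pct_of_measured))
}
print(res$regression)
```

```
RB 350             QY 0.0570  CUE 0.610  cover 0.97  capture 0.958  mass % 100.0
RB 300 + FR 50     QY 0.0580  CUE 0.610  cover 0.99  capture 0.980  mass % 100.0
white 350          QY 0.0573  CUE 0.610  cover 0.97  capture 0.935  mass % 100.0
white 300 + FR 50  QY 0.0582  CUE 0.610  cover 0.99  capture 0.945  mass % 100.0
<capture_regression> pooled: slope 5.162, intercept 0.006139, r2 0.998, n 72
              group    slope    intercept        r2  n
1    RB 300 + FR 50 5.190031 0.0056933315 0.9979954 18
2            RB 350 5.127966 0.0009300983 0.9998911 18
3 white 300 + FR 50 5.173862 0.0194872514 0.9961508 18
4         white 350 5.137208 0.0036510747 0.9995821 18
max pairwise relative slope difference: 0.012
```

Reading the output: all four treatments were generated with the same true
quantum yield (0.057) and mature CUE (0.61), and the pipeline recovers both
from the raw streams and images. The far-red treatments reach higher final
ground cover and photon capture — their growth advantage — while the
regression of daily gross photosynthesis on photon capture shows a common
slope across treatments (pairwise slope spread ~1%), i.e. equal
photosynthetic efficiency per captured photon. The mass-balance column
checks the gas-exchange chain: dry mass predicted from cumulative daily
carbon gain is ~100% of the generator's harvest biomass.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "canopyflux.R", package = "canopyflux")`) with
`simulate` and `analyze` subcommands operating on a plain-file experiment
directory.

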