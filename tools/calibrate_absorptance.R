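# Regenerates the constants in .absorptance_profile_params: solves the
# synthetic leaf absorptance curve parameters so that the spectrum-weighted
# single-layer photon absorption under the four default treatment spectra
# equals the reference values 0.927 / 0.798 / 0.838 / 0.686.
library(canopyflux)

grid <- 380:780
sps <- lapply(default_treatment_specs(), make_led_spectrum)
curve <- canopyflux:::.absorptance_curve
wabs <- function(sp, a) leaf_photon_absorption(sp, absorptance_spectrum(grid, a))

oc <- optim(c(0.95, 0.25), function(p) {
  a <- curve(grid, p[1], p[2], 0.45)
  (wabs(sps[["RB 350"]], a) - 0.927)^2 +
    (wabs(sps[["white 350"]], a) - 0.838)^2
})
cat("control: peak", oc$par[1], "dip", oc$par[2], "floor_fr 0.45\n")

of <- optim(c(0.35, 0.25), function(p) {
  a <- curve(grid, 0.88, p[1], p[2])
  (wabs(sps[["RB 300 + FR 50"]], a) - 0.798)^2 +
    (wabs(sps[["white 300 + FR 50"]], a) - 0.686)^2
})
cat("fr_grown: peak 0.88 dip", of$par[1], "floor_fr", of$par[2], "\n")
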