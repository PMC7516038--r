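Package: canopyflux
Title: Canopy Gas Exchange, Photon Capture, and Quantum Yield Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Decomposes whole-canopy growth measured in steady-state gas-exchange
    chambers into its three mechanistic components: canopy photon capture,
    canopy quantum yield for CO2 fixation, and carbon use efficiency.
    Provides tools for LED treatment spectra (waveband fluxes, daily light
    integral, phytochrome photoequilibrium, spectrum-weighted leaf photon
    absorption), for reducing a multiplexed chamber infra-red gas analyzer
    stream to per-chamber net CO2 flux and daily carbon metrics, for
    estimating daily canopy photon capture from top-down images with a
    Beer-Lambert multilayer correction, and for combining the two into canopy
    quantum yield. A synthetic-experiment generator produces treatment
    spectra, canopy growth trajectories, chamber CO2 streams, and canopy
    images with recorded ground truth, so every pipeline stage can be tested
    end to end without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
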