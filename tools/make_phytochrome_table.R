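# Regenerates inst/extdata/phytochrome_coefficients_synthetic.csv.
# The band amplitudes were chosen so that compute_ppe() with the default
# treatment spectra lands near the photoequilibria published coefficient
# sets give for narrow-band red/blue and white LED sources.
grid <- seq(380, 780, by = 2)
g <- function(c, s) exp(-0.5 * ((grid - c) / s)^2)
sr <- g(666, 25) + 0.25 * g(625, 28) + 0.15 * g(430, 35) + 0.045 * g(550, 60)
sfr <- 0.50 * g(730, 28) + 0.08 * g(665, 28) + 0.055 * g(430, 40) +
  0.012 * g(550, 60)
con <- file("inst/extdata/phytochrome_coefficients_synthetic.csv", "w")
writeLines(c(
  "# Synthetic phytochrome photoconversion coefficient table.",
  "# Relative photoconversion cross-sections of the Pr (sigma_r) and Pfr",
  "# (sigma_fr) forms, built from smooth Gaussian absorption bands (Pr: red",
  "# band at 666 nm, minor blue band; Pfr: far-red band at 730 nm with red",
  "# and blue shoulders) and scaled to reproduce the photoequilibria that",
  "# published coefficient sets give for narrow-band LED sources.",
  "# Regenerate with tools/make_phytochrome_table.R.",
  "wavelength_nm,sigma_r,sigma_fr"), con)
write.table(data.frame(grid, round(sr, 6), round(sfr, 6)), con,
            sep = ",", row.names = FALSE, col.names = FALSE)
close(con)
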