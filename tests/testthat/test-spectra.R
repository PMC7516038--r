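test_that("band integration matches closed forms and a fine-grid oracle", {
  flat <- flat_spectrum(1)
  expect_equal(integrate_photon_flux(flat, waveband(400, 500)), 100)
  expect_equal(integrate_photon_flux(flat_spectrum(0), waveband(420, 600)), 0)

  # Gaussian peak of area 50 fully inside the blue band, against trapezoidal
  # quadrature of the same curve on a 0.01 nm grid
  peak <- gaussian_spectrum(450, 5, 50)
  fine <- seq(400, 500, by = 0.01)
  y <- 50 * stats::dnorm(fine, 450, 5)
  oracle <- sum(diff(fine) * (y[-length(y)] + y[-1]) / 2)
  expect_equal(oracle, 50, tolerance = 1e-8)
  expect_equal(integrate_photon_flux(peak, waveband(400, 500)), oracle,
               tolerance = 1e-4)

  expect_error(integrate_photon_flux(flat, waveband(300, 500)), "outside")
  expect_error(waveband(600, 500))
})

test_that("waveband fractions partition the 400-750 nm flux", {
  fr <- waveband_fractions(flat_spectrum(1))
  expect_equal(unname(fr["blue"]), 100 / 350)
  expect_equal(sum(fr), 1)

  narrow <- gaussian_spectrum(450, 4, 10)
  fr2 <- waveband_fractions(narrow)
  expect_equal(unname(fr2["blue"]), 1, tolerance = 1e-9)
  expect_equal(unname(fr2["red"]), 0, tolerance = 1e-12)

  # sums to one and band additivity for arbitrary positive spectra
  set.seed(42)
  grid <- 380:780
  for (i in 1:20) {
    sp <- spectral_distribution(grid, stats::runif(length(grid)))
    expect_equal(sum(waveband_fractions(sp)), 1, tolerance = 1e-9)
    par <- integrate_photon_flux(sp, waveband(400, 700))
    bands <- standard_wavebands()
    expect_equal(integrate_photon_flux(sp, bands$blue) +
                   integrate_photon_flux(sp, bands$green) +
                   integrate_photon_flux(sp, bands$red),
                 par, tolerance = 1e-9)
  }
  expect_error(waveband_fractions(flat_spectrum(0)), "zero total")
})

test_that("daily light integral converts PPFD and photoperiod", {
  expect_equal(daily_light_integral(350, 14), 17.64)
  expect_equal(daily_light_integral(0, 14), 0)
  expect_equal(daily_light_integral(100, 10), 3.6)
  expect_error(daily_light_integral(-1, 10), "non-negative")
})

test_that("phytochrome photoequilibrium behaves at its closed-form limits", {
  grid <- 380:780
  # spectrum supported only where sigma_fr = 0 and sigma_r > 0
  co <- photoconversion_coefficients(grid, sigma_r = rep(1, length(grid)),
                                     sigma_fr = as.numeric(grid > 700))
  red_only <- gaussian_spectrum(660, 5, 100)
  expect_equal(compute_ppe(red_only, co), 1, tolerance = 1e-9)

  co_eq <- photoconversion_coefficients(grid, rep(0.4, length(grid)),
                                        rep(0.4, length(grid)))
  expect_equal(compute_ppe(flat_spectrum(2), co_eq), 0.5)

  zero_band <- photoconversion_coefficients(grid, as.numeric(grid < 500),
                                            as.numeric(grid < 500))
  expect_error(compute_ppe(gaussian_spectrum(700, 3, 10), zero_band),
               "undefined")
})

test_that("PPE and leaf absorption are invariant to spectrum scaling", {
  co <- default_photoconversion_coefficients()
  leaf <- synthetic_leaf_absorptance("control")
  sp <- make_led_spectrum(default_treatment_specs()[["white 350"]])
  sp10 <- spectral_distribution(sp$wavelength_nm, sp$flux_density * 10)
  expect_equal(compute_ppe(sp, co), compute_ppe(sp10, co), tolerance = 1e-12)
  expect_equal(leaf_photon_absorption(sp, leaf),
               leaf_photon_absorption(sp10, leaf), tolerance = 1e-12)
})

test_that("the red/blue spectrum sits near the reference photoequilibrium", {
  sp <- make_led_spectrum(default_treatment_specs()[["RB 350"]])
  expect_equal(compute_ppe(sp), 0.87, tolerance = 0.05 / 0.87)
})

test_that("leaf photon absorption is a flux-weighted absorptance mean", {
  grid <- 380:780
  sp <- flat_spectrum(1)
  expect_equal(leaf_photon_absorption(
    sp, absorptance_spectrum(grid, rep(1, length(grid)))), 1)
  expect_equal(leaf_photon_absorption(
    sp, absorptance_spectrum(grid, rep(0.5, length(grid)))), 0.5)

  # flux over 400-750 only, absorptance 0.9 below 700 and 0.2 above:
  # (0.9 x 300 + 0.2 x 50) / 350 = 0.8, up to the step-edge quadrature cell
  sp400 <- spectral_distribution(grid, as.numeric(grid >= 400 & grid <= 750))
  step <- absorptance_spectrum(grid, ifelse(grid <= 700, 0.9, 0.2))
  expect_equal(leaf_photon_absorption(sp400, step), 0.8, tolerance = 5e-3)

  # monotone in absorptance
  set.seed(7)
  for (i in 1:10) {
    a1 <- stats::runif(length(grid))
    a2 <- pmin(1, a1 + stats::runif(length(grid), 0, 0.3))
    sp_r <- spectral_distribution(grid, stats::runif(length(grid)))
    expect_gte(leaf_photon_absorption(sp_r, absorptance_spectrum(grid, a2)),
               leaf_photon_absorption(sp_r, absorptance_spectrum(grid, a1)))
  }
  expect_error(leaf_photon_absorption(
    flat_spectrum(0), absorptance_spectrum(grid, rep(0.5, length(grid)))),
    "zero total")
})

test_that("spectral containers validate their invariants", {
  expect_error(spectral_distribution(500:400, rep(1, 101)), "increasing")
  expect_error(spectral_distribution(380:780, rep(-1, 401)), "non-negative")
  expect_error(spectral_distribution(400:600, rep(1, 201)), "span")
  expect_error(absorptance_spectrum(380:780, rep(1.5, 401)), "\\[0, 1\\]")
  expect_error(photoconversion_coefficients(1:3, c(1, 1, 1), c(-1, 0, 0)),
               "non-negative")
})
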