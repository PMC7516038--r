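test_that("generated LED spectra honour the normalization contract", {
  specs <- default_treatment_specs()
  for (sp in specs) {
    s <- make_led_spectrum(sp)
    expect_equal(integrate_photon_flux(s, waveband(400, 750)),
                 sp$total_ppfd, tolerance = 1e-6)
  }
})

test_that("default treatment spectra hit the published waveband fractions", {
  specs <- default_treatment_specs()
  fr_rb <- waveband_fractions(make_led_spectrum(specs[["RB 350"]]))
  expect_equal(unname(fr_rb["blue"]), 0.315, tolerance = 0.003 / 0.315)

  fr_frb <- waveband_fractions(make_led_spectrum(specs[["RB 300 + FR 50"]]))
  expect_equal(unname(fr_frb["far_red"]), 50 / 350,
               tolerance = 0.003 / (50 / 350))
  expect_equal(unname(fr_frb["blue"]), 0.315, tolerance = 0.003 / 0.315)

  fr_w <- waveband_fractions(make_led_spectrum(specs[["white 350"]]))
  expect_equal(unname(fr_w["green"]), 0.452, tolerance = 0.003 / 0.452)
})

test_that("unreachable waveband targets raise a calibration error", {
  bad <- treatment_spec("bad", 350,
                        data.frame(center_nm = 663, sd_nm = 8.5,
                                   band = "red"),
                        c(red = 0.2))
  expect_error(make_led_spectrum(bad), "calibration error")
})

test_that("canopy growth is logistic with an exponential early phase", {
  gp <- growth_params()
  g <- simulate_canopy_growth(gp, 18)
  expect_equal(nrow(g), 18)
  expect_true(all(diff(g$leaf_area_m2) > 0))
  expect_true(all(g$cover >= 0 & g$cover <= 1))
  expect_true(all(g$layers >= 1))
  # early phase: daily log-increments close to the nominal rate
  early <- diff(log(g$leaf_area_m2[1:5]))
  expect_equal(mean(early), gp$rgr_d, tolerance = 0.02)

  # zero growth rate: constant area
  flat <- simulate_canopy_growth(growth_params(rgr_d = 0), 10)
  expect_equal(flat$leaf_area_m2, rep(gp$initial_area_m2, 10))

  # a far-red multiplier of one reproduces the control trajectory
  g1 <- simulate_canopy_growth(growth_params(fr_expansion = 1), 18, fr = TRUE)
  g0 <- simulate_canopy_growth(growth_params(fr_expansion = 1), 18, fr = FALSE)
  expect_equal(g1, g0)
})

test_that("far-red expansion yields the reference harvest leaf-area contrast", {
  gp <- growth_params()
  ctrl <- simulate_canopy_growth(gp, 18, fr = FALSE)
  fr <- simulate_canopy_growth(gp, 18, fr = TRUE)
  expect_equal(fr$leaf_area_m2[18] / ctrl$leaf_area_m2[18], 1.43,
               tolerance = 0.1 / 1.43)
})

test_that("chamber streams are reproducible and noiselessly invertible", {
  sched <- sampling_schedule(2)
  phys0 <- physiology_params(noise_sd = 0)
  capture <- cbind(seq(0.1, 0.6, length.out = 3),
                   seq(0.15, 0.7, length.out = 3))
  s1 <- simulate_chamber_stream(capture, 350, phys0, sched, seed = 4)
  s2 <- simulate_chamber_stream(capture, 350, phys0, sched, seed = 4)
  expect_identical(s1$stream, s2$stream)

  sn <- simulate_chamber_stream(capture, 350,
                                physiology_params(noise_sd = 0.5),
                                sched, seed = 4)
  expect_false(identical(s1$stream$delta_co2_umol_mol,
                         sn$stream$delta_co2_umol_mol))

  # noiseless round trip: daily metrics recover the generated truth < 0.5%
  rec <- demultiplex_stream(s1$stream, sched)
  flux <- flux_series(rec, 0.17)
  out <- daily_summaries(flux)
  conv <- carbon_conversion()
  truth_pg <- gross_photosynthesis(s1$pnet_light_umol * 3600e-6,
                                   s1$rdark_umol * 3600e-6, conv)
  for (ch in 1:2) {
    got <- out$pgross_g_d[out$chamber_id == ch]
    expect_equal(got, unname(truth_pg[, ch]), tolerance = 5e-3)
  }
  # infeasible physiology is rejected up front
  expect_error(physiology_params(cue_mature = 1.2), "\\(0, 1\\]")
  expect_error(physiology_params(true_quantum_yield = 0.2), "0.125")
})

test_that("rendered canopy images realize the requested green fraction", {
  blank <- render_canopy_image(0, size = 60, seed = 1)
  expect_equal(ground_cover_fraction(blank), 0)
  full <- render_canopy_image(1, size = 60, seed = 1)
  expect_equal(ground_cover_fraction(full), 1)

  img <- render_canopy_image(0.4, size = 160, seed = 9)
  expect_equal(attr(img, "realized_cover"), 0.4, tolerance = 0.01 / 0.4)
  expect_equal(ground_cover_fraction(img), 0.4, tolerance = 0.01 / 0.4)

  # reproducible under a fixed seed
  expect_identical(render_canopy_image(0.3, size = 80, seed = 2),
                   render_canopy_image(0.3, size = 80, seed = 2))
  expect_error(render_canopy_image(1.3), "\\[0, 1\\]")
})

test_that("the generator's biomass bookkeeping closes exactly", {
  sim <- simulate_experiment(default_treatment_specs()[1], days = 6,
                             phys = physiology_params(noise_sd = 0),
                             schedule = sampling_schedule(1),
                             seed = 5, images = FALSE)
  td <- sim$truth$daily
  expect_equal(diff(td$biomass_g), td$dcg_g_d[-1], tolerance = 1e-12)
  pm <- predict_harvest_mass(td$dcg_g_d, td$initial_mass_g[1],
                             sim$harvest$measured_mass_g)
  expect_equal(pm$percent_of_measured, 100, tolerance = 1e-9)
})

test_that("simulated experiments are reproducible and internally consistent", {
  specs <- default_treatment_specs()[c(1, 2)]
  sim1 <- simulate_experiment(specs, days = 4, seed = 8, images = FALSE,
                              schedule = sampling_schedule(2))
  sim2 <- simulate_experiment(specs, days = 4, seed = 8, images = FALSE,
                              schedule = sampling_schedule(2))
  expect_identical(sim1$stream, sim2$stream)
  expect_identical(sim1$truth$daily, sim2$truth$daily)

  # truth capture is consistent with its own cover/layers via Beer-Lambert
  td <- sim1$truth$daily
  k <- sim1$treatments$k[td$chamber_id]
  expect_equal(td$capture,
               td$cover * beer_lambert_absorption(k, td$layers),
               tolerance = 1e-12)
})

test_that("a simulated experiment round-trips through the directory format", {
  sim <- simulate_experiment(default_treatment_specs()[1], days = 3,
                             schedule = sampling_schedule(1), seed = 6,
                             images = TRUE, image_size = 60)
  dir <- tempfile("expdir")
  on.exit(unlink(dir, recursive = TRUE))
  write_experiment(sim, dir)
  expect_true(file.exists(file.path(dir, "stream.csv")))
  expect_true(file.exists(file.path(dir, "chamber1_day3.png")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  stream <- read_stream_csv(file.path(dir, "stream.csv"))
  expect_equal(nrow(stream), nrow(sim$stream))
  sp <- read_spectrum_csv(file.path(dir, "spectrum_chamber1.csv"))
  expect_equal(sp$flux_density, sim$spectra[["1"]]$flux_density)
  leaf <- read_absorptance_csv(file.path(dir, "absorptance_chamber1.csv"))
  expect_equal(leaf$absorptance, sim$absorptance[["1"]]$absorptance)
})
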