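#' Treatment specification for the LED spectrum generator
#'
#' Describes one light treatment as a Gaussian mixture: component peaks
#' (center, width, and the waveband each one controls) plus the target
#' waveband fractions of total 400--750 nm flux.
#'
#' @param name Treatment name.
#' @param total_ppfd Total 400--750 nm photon flux (umol m-2 s-1), > 0.
#' @param peaks Data.frame `center_nm, sd_nm, band` with one row per LED
#'   component; `band` is the [standard_wavebands()] label the component is
#'   calibrated against.
#' @param target_fractions Named vector of target waveband fractions for the
#'   bands that have a dedicated component; remaining flux floats into the
#'   uncontrolled bands through the component tails.
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(name, total_ppfd, peaks, target_fractions) {
  if (total_ppfd <= 0) stop("total_ppfd must be positive")
  stopifnot(is.data.frame(peaks),
            all(c("center_nm", "sd_nm", "band") %in% names(peaks)))
  if (any(peaks$sd_nm <= 0)) stop("peak widths must be positive")
  if (!all(peaks$band %in% names(target_fractions)))
    stop("every peak band needs a target fraction")
  structure(list(name = name, total_ppfd = total_ppfd, peaks = peaks,
                 target_fractions = target_fractions),
            class = "treatment_spec")
}

#' Default four-treatment specification set
#'
#' The bundled treatments mirror a red/blue vs white factorial with and
#' without far-red substitution: `RB 350`, `RB 300 + FR 50`, `white 350`,
#' `white 300 + FR 50`. All four have a total 400--750 nm flux of
#' 350 umol m-2 s-1 and 31.5% blue photons; the far-red treatments replace
#' 50 umol m-2 s-1 (1/7 of total) of 400--700 nm photons with 700--750 nm
#' photons. Red/blue sources peak at 443 and 663 nm, white at 450 nm with a
#' broad phosphor secondary peak at 567 nm, and far-red at 730 nm. The white
#' green:red balance targets the 45.2:23.3 ratio of a cool-white phosphor.
#'
#' @return Named list of [treatment_spec()] objects.
#' @export
default_treatment_specs <- function() {
  fr <- 50 / 350
  rb_peaks <- data.frame(center_nm = c(443, 663), sd_nm = c(7.6, 8.5),
                         band = c("blue", "red"))
  # phosphor widths solved so the green:red tail ratio of the 567 nm hump
  # makes the 45.2:23.3 target balance exactly; the white + FR variant uses
  # a slightly wider hump because its 700-750 nm band is pinned by the
  # far-red component rather than fed by the phosphor tail
  w_peaks <- data.frame(center_nm = c(450, 567), sd_nm = c(8.5, 61.1187),
                        band = c("blue", "green"))
  wfr_peaks <- data.frame(center_nm = c(450, 567), sd_nm = c(8.5, 63.7834),
                          band = c("blue", "green"))
  frp <- data.frame(center_nm = 730, sd_nm = 10.6, band = "far_red")
  white_green_300 <- (300 - 0.315 * 350) * 45.2 / (45.2 + 23.3) / 350
  list(
    "RB 350" = treatment_spec(
      "RB 350", 350, rb_peaks,
      c(blue = 0.315, red = 1 - 0.315)),
    "RB 300 + FR 50" = treatment_spec(
      "RB 300 + FR 50", 350, rbind(rb_peaks, frp),
      c(blue = 0.315, red = 1 - 0.315 - fr, far_red = fr)),
    "white 350" = treatment_spec(
      "white 350", 350, w_peaks,
      c(blue = 0.315, green = 0.452)),
    "white 300 + FR 50" = treatment_spec(
      "white 300 + FR 50", 350, rbind(wfr_peaks, frp),
      c(blue = 0.315, green = white_green_300, far_red = fr))
  )
}

#' Generate an LED treatment spectrum from a specification
#'
#' Builds a Gaussian-mixture spectrum on the default 380--780 nm, 1 nm grid.
#' Component weights are calibrated by iterative proportional fitting so that
#' the waveband fraction of each component's own band matches the
#' specification target, then the whole spectrum is rescaled so the
#' 400--750 nm integral equals `total_ppfd` exactly.
#'
#' @param spec A [treatment_spec()].
#' @param grid_nm Wavelength grid, default `380:780`.
#' @param tol Calibration tolerance on the controlled band fractions
#'   (default 2e-4, i.e. 0.02 percentage points — an order of magnitude
#'   tighter than the 0.3 pp calibration contract); fractions further than
#'   ten times `tol` from target after fitting raise a calibration error.
#' @return A [spectral_distribution()].
#' @export
make_led_spectrum <- function(spec, grid_nm = 380:780, tol = 2e-4) {
  stopifnot(inherits(spec, "treatment_spec"))
  comps <- lapply(seq_len(nrow(spec$peaks)), function(i) {
    stats::dnorm(grid_nm, spec$peaks$center_nm[i], spec$peaks$sd_nm[i])
  })
  bands <- standard_wavebands()
  band_frac <- function(flux) {
    s <- spectral_distribution(grid_nm, flux)
    waveband_fractions(s)
  }
  w <- rep(1, length(comps))
  target <- spec$target_fractions[spec$peaks$band]
  for (iter in 1:200) {
    flux <- Reduce(`+`, Map(`*`, comps, w))
    fr <- band_frac(flux)
    cur <- fr[spec$peaks$band]
    if (max(abs(cur - target)) < tol) break
    w <- w * as.numeric(target / cur)
    if (any(!is.finite(w)) || any(w <= 0))
      stop("calibration error: target waveband fractions unreachable")
  }
  flux <- Reduce(`+`, Map(`*`, comps, w))
  fr <- band_frac(flux)
  if (max(abs(fr[spec$peaks$band] - target)) > 10 * tol)
    stop("calibration error: target waveband fractions unreachable")
  s <- spectral_distribution(grid_nm, flux)
  total <- integrate_photon_flux(s, waveband(400, 750, "total"))
  spectral_distribution(grid_nm, flux * spec$total_ppfd / total)
}

# Smooth synthetic leaf absorptance curve: a high visible plateau with a
# green dip, falling sigmoidally across the red edge to a far-red floor.
.absorptance_curve <- function(grid_nm, peak, dip, floor_fr,
                               dip_center = 555, dip_sd = 45,
                               fall_center = 712, fall_width = 9) {
  base <- peak - dip * exp(-0.5 * ((grid_nm - dip_center) / dip_sd)^2)
  f <- 1 / (1 + exp((grid_nm - fall_center) / fall_width))
  pmin(1, pmax(0, floor_fr + (base - floor_fr) * f))
}

#' Synthetic leaf absorptance profiles
#'
#' Two bundled absorptance spectra: `control` for leaves developed under
#' red/blue or white light, and `fr_grown` for the thinner, lower-chlorophyll
#' leaves developed under far-red substitution (lower peak absorptance, a
#' deeper green dip, and a lower far-red floor). The curve parameters are
#' calibrated so that the spectrum-weighted single-layer photon absorption
#' under the four [default_treatment_specs()] spectra reproduces the
#' reference values 0.927 (RB), 0.798 (RB + FR), 0.838 (white) and
#' 0.686 (white + FR).
#'
#' @param profile `"control"` or `"fr_grown"`.
#' @param grid_nm Wavelength grid, default `380:780`.
#' @return An [absorptance_spectrum()].
#' @export
synthetic_leaf_absorptance <- function(profile = c("control", "fr_grown"),
                                       grid_nm = 380:780) {
  profile <- match.arg(profile)
  p <- .absorptance_profile_params[[profile]]
  absorptance_spectrum(
    grid_nm,
    .absorptance_curve(grid_nm, p["peak"], p["dip"], p["floor_fr"]))
}

# Calibrated against the reference single-layer absorptions (see
# synthetic_leaf_absorptance); regenerate with tools/calibrate_absorptance.R.
.absorptance_profile_params <- list(
  control  = c(peak = 0.9409621, dip = 0.2063479, floor_fr = 0.45),
  fr_grown = c(peak = 0.88, dip = 0.3411438, floor_fr = 0.3588175)
)

#' Canopy growth parameters for the experiment generator
#'
#' Defaults emulate a small lettuce canopy (four plants on a 0.17 m2 chamber
#' floor) grown for ~18 days: logistic total leaf-area growth whose early
#' phase is exponential, a projected-area model that tracks total area until
#' an overlap-onset cover and then saturates towards canopy closure, and a
#' far-red expansion multiplier on the relative growth rate that yields a
#' ~1.4-fold leaf-area increase at harvest.
#'
#' @param initial_area_m2 Total leaf area on day 1 (m2).
#' @param rgr_d Early-phase relative growth rate (d-1).
#' @param sat_area_m2 Logistic saturation leaf area (m2).
#' @param fr_expansion Multiplier on `rgr_d` under far-red substitution.
#' @param onset_cover Ground-cover fraction at which leaves begin to overlap.
#' @param lma_g_m2 Leaf dry mass per area (g m-2), used to set the initial
#'   dry mass.
#' @param root_fraction Fraction of plant dry mass in roots.
#' @param absorptance_profile `"control"` or `"fr_grown"`.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(initial_area_m2 = 0.004, rgr_d = 0.304,
                          sat_area_m2 = 0.55, fr_expansion = 1.225,
                          onset_cover = 0.5, lma_g_m2 = 28,
                          root_fraction = 0.15,
                          absorptance_profile = "control") {
  vals <- c(initial_area_m2, sat_area_m2, fr_expansion, onset_cover,
            lma_g_m2)
  if (any(vals <= 0) || rgr_d < 0) stop("growth parameters must be positive")
  if (sat_area_m2 < initial_area_m2)
    stop("saturation area must be >= initial area")
  structure(list(initial_area_m2 = initial_area_m2, rgr_d = rgr_d,
                 sat_area_m2 = sat_area_m2, fr_expansion = fr_expansion,
                 onset_cover = onset_cover, lma_g_m2 = lma_g_m2,
                 root_fraction = root_fraction,
                 absorptance_profile = absorptance_profile),
            class = "growth_params")
}

#' Physiology parameters for the experiment generator
#'
#' @param true_quantum_yield Canopy quantum yield used to generate fluxes
#'   (mol CO2 per mol absorbed photons), in (0, 0.125].
#' @param cue_mature Mature-plant carbon use efficiency target, in (0, 1].
#' @param cue_seedling Effective CUE on day 1; the generator ramps CUE
#'   linearly from this value to `cue_mature` over `cue_ramp_days` days,
#'   emulating the rise observed in young seedlings.
#' @param cue_ramp_days Days over which the seedling CUE ramp completes.
#' @param noise_sd Gaussian noise SD on the per-second CO2 differential
#'   (umol mol-1).
#' @param flow_start_mol_s,flow_end_mol_s Chamber air flow on the first and
#'   last day (mol s-1); interpolated linearly in between, matching the
#'   practice of raising flow as canopies grow.
#' @return An object of class `physiology_params`.
#' @export
physiology_params <- function(true_quantum_yield = 0.057,
                              cue_mature = 0.61, cue_seedling = 0.4,
                              cue_ramp_days = 10, noise_sd = 0.5,
                              flow_start_mol_s = 0.011,
                              flow_end_mol_s = 0.037) {
  if (true_quantum_yield <= 0 || true_quantum_yield > 0.125)
    stop("true_quantum_yield must lie in (0, 0.125]")
  if (cue_mature <= 0 || cue_mature > 1 || cue_seedling <= 0 ||
      cue_seedling > 1)
    stop("CUE values must lie in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (flow_start_mol_s <= 0 || flow_end_mol_s <= 0)
    stop("flows must be positive")
  structure(list(true_quantum_yield = true_quantum_yield,
                 cue_mature = cue_mature, cue_seedling = cue_seedling,
                 cue_ramp_days = cue_ramp_days, noise_sd = noise_sd,
                 flow_start_mol_s = flow_start_mol_s,
                 flow_end_mol_s = flow_end_mol_s),
            class = "physiology_params")
}

#' Simulate the daily canopy growth trajectory of one chamber
#'
#' Total leaf area follows a logistic trajectory
#' `A(t) = K A0 e^(r t) / (K + A0 (e^(r t) - 1))` whose early phase is
#' exponential with rate `r` (times the far-red expansion multiplier when
#' `fr = TRUE`). Projected ground cover equals total area until the
#' overlap-onset area `A_on = onset_cover x chamber area`, after which it
#' saturates smoothly (and continuously in value and slope) towards the
#' chamber area. Leaf layers are total over projected, floored at 1.
#'
#' @param params A [growth_params()].
#' @param days Number of days, >= 1.
#' @param chamber_area_m2 Chamber ground area (m2).
#' @param fr Apply the far-red expansion multiplier?
#' @return Data.frame `day, leaf_area_m2, projected_m2, cover, layers`.
#' @export
simulate_canopy_growth <- function(params, days, chamber_area_m2 = 0.17,
                                   fr = FALSE) {
  stopifnot(inherits(params, "growth_params"))
  r <- params$rgr_d * if (fr) params$fr_expansion else 1
  t <- seq_len(days) - 1
  a0 <- params$initial_area_m2
  k <- params$sat_area_m2
  area <- k * a0 * exp(r * t) / (k + a0 * (exp(r * t) - 1))
  a_on <- params$onset_cover * chamber_area_m2
  proj <- ifelse(
    area <= a_on, area,
    chamber_area_m2 - (chamber_area_m2 - a_on) *
      exp(-(area - a_on) / (chamber_area_m2 - a_on)))
  data.frame(day = seq_len(days), leaf_area_m2 = area, projected_m2 = proj,
             cover = proj / chamber_area_m2,
             layers = pmax(1, area / proj))
}

#' Simulate the raw multiplexed analyzer stream of an experiment
#'
#' Generates the 1 Hz record stream of a single analyzer multiplexed over all
#' chambers. For each chamber and day the light-period gross uptake rate is
#' `true_QY x incident flux x capture` (umol CO2 m-2 s-1); the respiration
#' rate is set from the day's effective CUE as
#' `R = photoperiod_h x P_gross_rate x (1 - CUE) / 24`, so that the daily
#' metrics computed from the stream recover the target CUE exactly in the
#' noiseless case. The per-second CO2 differential is
#' `flux x area / flow` plus Gaussian noise, multiplexed according to the
#' schedule (chamber `c` occupies slot `c` of every cycle).
#'
#' @param capture Matrix `days x chambers` of daily canopy photon-capture
#'   fractions.
#' @param incident_ppfd Incident photon flux (umol m-2 s-1), recycled per
#'   chamber.
#' @param phys A [physiology_params()].
#' @param schedule A [sampling_schedule()] whose `n_chambers` matches
#'   `ncol(capture)`.
#' @param conv A [carbon_conversion()].
#' @param seed Integer seed; the stream is reproducible for a fixed seed.
#' @param qy_multipliers Optional per-chamber multipliers on the true quantum
#'   yield (default all 1): lets a generated experiment depart from the
#'   spectrally flat quantum-yield hypothesis so the pipeline's ability to
#'   detect such departures can be tested.
#' @return List with `stream` (raw record data.frame), and the per-day truth
#'   matrices `pnet_light_umol`, `rdark_umol`, `flow_mol_s`, `cue`.
#' @export
simulate_chamber_stream <- function(capture, incident_ppfd, phys, schedule,
                                    conv = carbon_conversion(), seed = 1,
                                    qy_multipliers = NULL) {
  stopifnot(inherits(phys, "physiology_params"),
            inherits(schedule, "sampling_schedule"),
            inherits(conv, "carbon_conversion"))
  capture <- as.matrix(capture)
  n_days <- nrow(capture)
  n_ch <- ncol(capture)
  if (n_ch != schedule$n_chambers)
    stop("schedule declares ", schedule$n_chambers, " chambers but capture has ",
         n_ch)
  incident_ppfd <- rep_len(incident_ppfd, n_ch)
  qy_multipliers <- rep_len(if (is.null(qy_multipliers)) 1 else qy_multipliers,
                            n_ch)
  if (any(qy_multipliers <= 0)) stop("qy_multipliers must be positive")

  day_idx <- seq_len(n_days)
  cue_day <- phys$cue_mature - (phys$cue_mature - phys$cue_seedling) *
    pmax(0, 1 - (day_idx - 1) / phys$cue_ramp_days)
  gross <- t(t(capture) *
               (phys$true_quantum_yield * qy_multipliers * incident_ppfd))
  resp <- conv$photoperiod_h * gross * (1 - cue_day) / 24
  if (any(resp < 0))
    stop("parameter error: target CUE implies negative respiration")
  pnet_light <- gross - resp
  flow <- matrix(rep(seq(phys$flow_start_mol_s, phys$flow_end_mol_s,
                         length.out = n_days), n_ch), ncol = n_ch)

  n_sec <- n_days * 86400
  t_s <- seq_len(n_sec) - 1
  ch <- (t_s %% schedule$cycle_s) %/% schedule$slot_s + 1L
  day <- t_s %/% 86400 + 1L
  light <- (t_s %% 86400) < conv$photoperiod_h * 3600
  idx <- cbind(day, ch)
  flux <- ifelse(light, pnet_light[idx], -resp[idx])
  fl <- flow[idx]
  set.seed(seed)
  delta <- flux * conv$ground_area_m2 / fl +
    if (phys$noise_sd > 0) stats::rnorm(n_sec, 0, phys$noise_sd) else 0
  stream <- data.frame(timestamp_s = t_s, chamber_id = ch, flow_mol_s = fl,
                       delta_co2_umol_mol = delta, light_on = light)
  list(stream = stream, pnet_light_umol = pnet_light, rdark_umol = -resp,
       flow_mol_s = flow, cue = cue_day)
}

#' Render a synthetic top-down canopy image with known green-pixel fraction
#'
#' Draws a rosette of green ellipses for each of four plants over a
#' soil-coloured background and scales the rosettes by binary search until
#' the realized green-pixel fraction is within `tol` of the request. Colours
#' are chosen so the default [ground_cover_fraction()] classifier labels
#' exactly the drawn pixels as plant.
#'
#' @param cover_fraction Requested green-pixel fraction in \[0, 1\].
#' @param size Image side length in pixels (square image), default 160.
#' @param seed Integer seed for leaf geometry and colour noise.
#' @param tol Tolerance on the realized fraction (default 0.003).
#' @return Numeric array `size x size x 3` in \[0, 1\] with the realized
#'   fraction in attribute `realized_cover`.
#' @export
render_canopy_image <- function(cover_fraction, size = 160, seed = 1,
                                tol = 0.003) {
  if (cover_fraction < 0 || cover_fraction > 1)
    stop("cover_fraction must lie in [0, 1]")
  set.seed(seed)
  xy <- seq(0, 1, length.out = size)
  px <- matrix(xy, size, size, byrow = TRUE)   # x by column
  py <- matrix(xy, size, size)                 # y by row

  centers <- expand.grid(x = c(0.28, 0.72), y = c(0.28, 0.72))
  centers$x <- centers$x + stats::runif(4, -0.04, 0.04)
  centers$y <- centers$y + stats::runif(4, -0.04, 0.04)
  leaves <- do.call(rbind, lapply(seq_len(4), function(p) {
    n_leaf <- 7
    ang <- stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n_leaf + 1)[-1]
    data.frame(
      cx = centers$x[p], cy = centers$y[p], theta = ang,
      ecc = stats::runif(n_leaf, 0.45, 0.65),
      len = stats::runif(n_leaf, 0.8, 1.2),
      offset = stats::runif(n_leaf, 0.35, 0.55))
  }))

  draw <- function(scale) {
    mask <- matrix(FALSE, size, size)
    if (scale <= 0) return(mask)
    for (i in seq_len(nrow(leaves))) {
      a <- leaves$len[i] * scale
      b <- a * leaves$ecc[i]
      th <- leaves$theta[i]
      cx <- leaves$cx[i] + cos(th) * leaves$offset[i] * a
      cy <- leaves$cy[i] + sin(th) * leaves$offset[i] * a
      dx <- px - cx; dy <- py - cy
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      mask <- mask | (u * u + v * v <= 1)
    }
    mask
  }

  if (cover_fraction < tol / 2) {
    mask <- matrix(FALSE, size, size)
  } else if (cover_fraction > 1 - tol / 2) {
    mask <- matrix(TRUE, size, size)
  } else {
    lo <- 0; hi <- 2
    if (mean(draw(hi)) < cover_fraction - tol)
      stop("requested cover exceeds achievable packing")
    mask <- NULL
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      m <- draw(mid)
      frac <- mean(m)
      if (abs(frac - cover_fraction) <= tol) { mask <- m; break }
      if (frac < cover_fraction) lo <- mid else hi <- mid
    }
    if (is.null(mask)) mask <- draw((lo + hi) / 2)
  }

  img <- array(0, c(size, size, 3))
  n_px <- size * size
  soil <- c(0.42, 0.36, 0.30)
  plant <- c(0.20, 0.55, 0.22)
  noise <- function(sd) stats::rnorm(n_px, 0, sd)
  for (c3 in 1:3) {
    ch <- matrix(soil[c3] + noise(0.02), size, size)
    ch[mask] <- plant[c3] + stats::rnorm(sum(mask), 0, 0.03)
    img[, , c3] <- pmin(1, pmax(0, ch))
  }
  # keep the classifier exact on synthetic images: enforce channel ordering
  g <- img[, , 2]
  img[, , 1][mask] <- pmin(img[, , 1][mask], g[mask] - 0.05)
  img[, , 3][mask] <- pmin(img[, , 3][mask], g[mask] - 0.05)
  img[, , 2][mask] <- pmax(g[mask], 0.2)
  img[, , 2][!mask] <- pmin(img[, , 2][!mask], img[, , 1][!mask] - 0.02)
  attr(img, "realized_cover") <- mean(mask)
  img
}

#' Simulate a complete synthetic canopy gas-exchange experiment
#'
#' Generates every input stream of a multi-chamber experiment with recorded
#' ground truth: treatment spectra, leaf absorptance, daily canopy growth,
#' the multiplexed analyzer stream, daily top-down canopy images, and the
#' harvest table. One chamber per treatment.
#'
#' @param treatments List of [treatment_spec()]s (default:
#'   [default_treatment_specs()]); chamber `i` runs treatment `i`. Treatments
#'   whose name contains `"FR"` use the far-red growth and absorptance
#'   parameters.
#' @param days Experiment length in days (default 18).
#' @param growth A [growth_params()].
#' @param phys A [physiology_params()].
#' @param conv A [carbon_conversion()].
#' @param schedule A [sampling_schedule()]; default 30 s sample / 40 s purge
#'   over the number of treatments.
#' @param seed Integer seed controlling all randomness.
#' @param images Render daily canopy images (default TRUE)?
#' @param image_size Image side length in pixels.
#' @param qy_multipliers Optional per-treatment multipliers on the true
#'   quantum yield; see [simulate_chamber_stream()].
#' @return An object of class `canopy_simulation`: list with `treatments`
#'   (data.frame), `spectra`, `absorptance` (named lists by chamber),
#'   `stream`, `images` (`images[[chamber]][[day]]`), `harvest`, and `truth`
#'   (list with per-day data.frame `daily` and all generator parameters).
#' @export
simulate_experiment <- function(treatments = default_treatment_specs(),
                                days = 18,
                                growth = growth_params(),
                                phys = physiology_params(),
                                conv = carbon_conversion(),
                                schedule = NULL, seed = 1,
                                images = TRUE, image_size = 160,
                                qy_multipliers = NULL) {
  n_ch <- length(treatments)
  if (is.null(schedule)) schedule <- sampling_schedule(n_ch)
  set.seed(seed)

  spectra <- list(); absorpt <- list(); leaf_abs <- numeric(n_ch)
  kvec <- numeric(n_ch); is_fr <- logical(n_ch)
  tr_names <- vapply(treatments, `[[`, character(1), "name")
  for (i in seq_len(n_ch)) {
    sp <- make_led_spectrum(treatments[[i]])
    is_fr[i] <- grepl("FR", tr_names[i], fixed = TRUE)
    leaf <- synthetic_leaf_absorptance(
      if (is_fr[i]) "fr_grown" else growth$absorptance_profile)
    spectra[[as.character(i)]] <- sp
    absorpt[[as.character(i)]] <- leaf
    leaf_abs[i] <- leaf_photon_absorption(sp, leaf)
    kvec[i] <- extinction_coefficient(leaf_abs[i])
  }

  cap <- matrix(0, days, n_ch)
  daily <- list()
  for (i in seq_len(n_ch)) {
    g <- simulate_canopy_growth(growth, days, conv$ground_area_m2,
                                fr = is_fr[i])
    g$chamber_id <- i
    g$capture <- canopy_capture(g$cover,
                                beer_lambert_absorption(kvec[i], g$layers))
    cap[, i] <- g$capture
    daily[[i]] <- g
  }

  ppfd <- vapply(treatments, `[[`, numeric(1), "total_ppfd")
  sim <- simulate_chamber_stream(cap, ppfd, phys, schedule, conv,
                                 seed = seed + 1L,
                                 qy_multipliers = qy_multipliers)

  # truth bookkeeping in daily metrics and biomass
  to_mol_h <- 3600 * 1e-6
  truth_daily <- do.call(rbind, lapply(seq_len(n_ch), function(i) {
    d <- daily[[i]]
    pnl <- sim$pnet_light_umol[, i] * to_mol_h
    rd <- sim$rdark_umol[, i] * to_mol_h
    d$pgross_g_d <- gross_photosynthesis(pnl, rd, conv)
    d$dcg_g_d <- daily_carbon_gain(pnl, rd, conv)
    d$cue <- sim$cue
    init_mass <- growth$initial_area_m2 * growth$lma_g_m2 /
      (1 - growth$root_fraction)
    d$biomass_g <- init_mass + cumsum(d$dcg_g_d)
    d$initial_mass_g <- init_mass
    d
  }))

  imgs <- NULL
  realized <- rep(NA_real_, nrow(truth_daily))
  if (images) {
    imgs <- lapply(seq_len(n_ch), function(i) {
      lapply(seq_len(days), function(d) {
        render_canopy_image(daily[[i]]$cover[d], size = image_size,
                            seed = seed * 1000L + i * 100L + d)
      })
    })
    names(imgs) <- as.character(seq_len(n_ch))
    realized <- unlist(lapply(seq_len(n_ch), function(i)
      vapply(imgs[[i]], attr, numeric(1), "realized_cover")))
  }
  truth_daily$cover_realized <- realized

  harvest <- do.call(rbind, lapply(seq_len(n_ch), function(i) {
    d <- truth_daily[truth_daily$chamber_id == i, ]
    data.frame(chamber_id = i, treatment = tr_names[i],
               leaf_area_m2 = d$leaf_area_m2[days],
               measured_mass_g = d$biomass_g[days],
               initial_mass_g = d$initial_mass_g[1])
  }))

  structure(list(
    treatments = data.frame(chamber_id = seq_len(n_ch),
                            treatment = tr_names, total_ppfd = ppfd,
                            dli = daily_light_integral(ppfd,
                                                       conv$photoperiod_h),
                            leaf_absorption = leaf_abs, k = kvec,
                            far_red = is_fr),
    spectra = spectra, absorptance = absorpt, stream = sim$stream,
    images = imgs, harvest = harvest,
    truth = list(daily = truth_daily, seed = seed, growth = growth,
                 phys = phys, conv = conv, schedule = schedule)),
    class = "canopy_simulation")
}

#' Write a simulated experiment to a directory of plain files
#'
#' Writes per-chamber spectrum CSVs, absorptance CSVs, the raw stream CSV,
#' daily canopy images (`chamber{ID}_day{D}.png`), the harvest CSV, and
#' `truth.json`.
#'
#' @param sim A `canopy_simulation` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "canopy_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(sim$spectra)) {
    write_spectrum_csv(sim$spectra[[ch]],
                       file.path(dir, sprintf("spectrum_chamber%s.csv", ch)))
    write_absorptance_csv(sim$absorptance[[ch]],
                          file.path(dir, sprintf("absorptance_chamber%s.csv", ch)))
  }
  write_stream_csv(sim$stream, file.path(dir, "stream.csv"))
  utils::write.csv(sim$harvest, file.path(dir, "harvest.csv"),
                   row.names = FALSE)
  if (!is.null(sim$images)) {
    for (ch in names(sim$images)) {
      for (d in seq_along(sim$images[[ch]])) {
        png::writePNG(sim$images[[ch]][[d]],
                      file.path(dir, sprintf("chamber%s_day%d.png", ch, d)))
      }
    }
  }
  truth <- sim$truth
  truth$daily <- truth$daily
  jsonlite::write_json(
    list(daily = truth$daily, seed = truth$seed,
         growth = unclass(truth$growth), phys = unclass(truth$phys),
         conv = unclass(truth$conv), schedule = unclass(truth$schedule),
         treatments = sim$treatments),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
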