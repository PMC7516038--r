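# Shared fixture builders; everything is generated in code at test time.

flat_spectrum <- function(level = 1, grid = 380:780) {
  spectral_distribution(grid, rep(level, length(grid)))
}

# Gaussian photon-flux peak with a given total area (umol m-2 s-1)
gaussian_spectrum <- function(center, sd, area, grid = 380:780) {
  spectral_distribution(grid, area * stats::dnorm(grid, center, sd))
}

# Raw multiplexed stream with constant per-chamber delta values; chamber c
# occupies slot c of each cycle, mirroring the generator's layout.
constant_stream <- function(n_seconds, schedule, delta_by_chamber,
                            flow = 0.02, light_on = TRUE) {
  t_s <- seq_len(n_seconds) - 1
  ch <- (t_s %% schedule$cycle_s) %/% schedule$slot_s + 1L
  data.frame(timestamp_s = t_s, chamber_id = ch, flow_mol_s = flow,
             delta_co2_umol_mol = delta_by_chamber[ch], light_on = light_on)
}

# One day of collapsed per-chamber flux records on a regular revisit grid
day_flux_series <- function(light_value, dark_value, cycle_s = 280,
                            photoperiod_h = 14, day0 = 0) {
  t_s <- seq(0, 86400 - 1, by = cycle_s) + day0 * 86400
  light <- (t_s %% 86400) < photoperiod_h * 3600
  out <- data.frame(timestamp_s = t_s, chamber_id = 1L,
                    pnet_umol_m2_s = ifelse(light, light_value, dark_value),
                    light_on = light)
  attr(out, "ground_area") <- 0.17
  out
}

# Synthetic canopy photo with an exactly known green-pixel fraction: a green
# disk over a soil background. Returns the image with the true fraction as
# attribute "true_fraction" (pixel-count oracle).
disk_image <- function(size = 100, radius_frac = 0.345) {
  xy <- seq(0, 1, length.out = size)
  px <- matrix(xy, size, size, byrow = TRUE)
  py <- matrix(xy, size, size)
  mask <- (px - 0.5)^2 + (py - 0.5)^2 <= radius_frac^2
  img <- array(0, c(size, size, 3))
  img[, , 1] <- ifelse(mask, 0.2, 0.45)
  img[, , 2] <- ifelse(mask, 0.6, 0.35)
  img[, , 3] <- ifelse(mask, 0.25, 0.3)
  attr(img, "true_fraction") <- mean(mask)
  img
}
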