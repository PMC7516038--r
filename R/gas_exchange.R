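#' Carbon conversion constants for daily canopy metrics
#'
#' Holds the constants that convert averaged chamber fluxes
#' (mol CO2 m-2 h-1) into daily canopy carbon metrics in grams of dry mass:
#' gross photosynthesis
#' \deqn{P_{gross} = (P_{net,light} + |R_{dark}|) \times t_{light} \times A \times c}
#' daily carbon gain
#' \deqn{DCG = (P_{net,light} \times t_{light} - |R_{dark}| \times t_{dark}) \times A \times c}
#' and carbon use efficiency \eqn{CUE = DCG / P_{gross}}, with chamber ground
#' area \eqn{A} and \eqn{c} grams of dry mass per mole of CO2 assimilated
#' (30 g mol-1 corresponds to a tissue carbon fraction of 0.4 g g-1).
#'
#' @param photoperiod_h Light period per day (h), default 14.
#' @param dark_h Dark period per day (h), default 10. Must satisfy
#'   `photoperiod_h + dark_h == 24`.
#' @param ground_area_m2 Chamber ground area (m2), default 0.17.
#' @param g_per_mol_co2 Grams dry mass per mol CO2 assimilated, default 30.
#' @return An object of class `carbon_conversion`.
#' @export
carbon_conversion <- function(photoperiod_h = 14, dark_h = 10,
                              ground_area_m2 = 0.17, g_per_mol_co2 = 30) {
  if (photoperiod_h <= 0 || dark_h < 0 || ground_area_m2 <= 0 ||
      g_per_mol_co2 <= 0)
    stop("all carbon_conversion fields must be positive")
  if (abs(photoperiod_h + dark_h - 24) > 1e-9)
    stop("photoperiod_h + dark_h must equal 24")
  structure(list(photoperiod_h = photoperiod_h, dark_h = dark_h,
                 ground_area_m2 = ground_area_m2,
                 g_per_mol_co2 = g_per_mol_co2),
            class = "carbon_conversion")
}

#' Multiplexer sampling schedule
#'
#' Describes how a single gas analyzer is shared between chambers: each
#' chamber is routed to the analyzer for `sample_s` seconds, after which the
#' tubing is purged for `purge_s` seconds before the next chamber is sampled.
#' With 4 chambers and the default 30 s + 40 s schedule each chamber is
#' revisited every 280 s.
#'
#' @param n_chambers Number of chambers sharing the analyzer.
#' @param sample_s Seconds of valid sampling per chamber visit (> 0).
#' @param purge_s Seconds of purge discarded between visits (>= 0).
#' @return An object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(n_chambers, sample_s = 30, purge_s = 40) {
  if (n_chambers < 1 || sample_s <= 0 || purge_s < 0)
    stop("invalid sampling schedule")
  structure(list(n_chambers = as.integer(n_chambers),
                 sample_s = sample_s, purge_s = purge_s,
                 slot_s = sample_s + purge_s,
                 cycle_s = n_chambers * (sample_s + purge_s)),
            class = "sampling_schedule")
}

#' Demultiplex a raw analyzer stream into per-chamber records
#'
#' Splits the 1 Hz record stream of a multiplexed analyzer into per-chamber
#' series according to a [sampling_schedule()]: readings taken during purge
#' windows are discarded, and (optionally) each chamber visit is collapsed to
#' a single record by discarding the first `window_discard_s` seconds of the
#' sampling window as equilibration and averaging the remainder.
#'
#' Slot boundaries are derived from the timestamps: the visit index is
#' `floor(timestamp / (sample_s + purge_s))` and the within-visit offset
#' `timestamp mod (sample_s + purge_s)`; offsets at or beyond `sample_s` are
#' purge seconds. Every record retained within one visit must carry the same
#' `chamber_id`, otherwise the stream is inconsistent with the schedule.
#'
#' @param records Data.frame with columns `timestamp_s`, `chamber_id`,
#'   `flow_mol_s`, `delta_co2_umol_mol`, `light_on` (the raw stream CSV
#'   layout), ordered by timestamp.
#' @param schedule A [sampling_schedule()].
#' @param window_discard_s Seconds discarded at the start of each sampling
#'   window before averaging (default 10). Must be `< sample_s`.
#' @param collapse If `TRUE` (default) average each visit to one record;
#'   if `FALSE` return the retained raw seconds.
#' @return Data.frame with the same columns; one row per chamber visit when
#'   `collapse = TRUE`.
#' @export
demultiplex_stream <- function(records, schedule, window_discard_s = 10,
                               collapse = TRUE) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  need <- c("timestamp_s", "chamber_id", "flow_mol_s",
            "delta_co2_umol_mol", "light_on")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  if (window_discard_s < 0 || window_discard_s >= schedule$sample_s)
    stop("window_discard_s must be in [0, sample_s)")
  if (is.unsorted(records$timestamp_s))
    stop("records must be ordered by timestamp")
  if (length(unique(records$chamber_id)) > schedule$n_chambers)
    stop("stream contains more chambers than the schedule declares")

  slot_s <- schedule$slot_s
  offset <- records$timestamp_s %% slot_s
  keep <- offset >= window_discard_s & offset < schedule$sample_s
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) return(r)
  visit <- r$timestamp_s %/% slot_s

  # one chamber per visit, else the stream disagrees with the schedule
  chk <- tapply(r$chamber_id, visit, function(x) length(unique(x)))
  if (any(chk > 1))
    stop("schedule mismatch: a sampling window contains multiple chambers")
  if (!collapse) {
    rownames(r) <- NULL
    return(r)
  }

  out <- data.frame(
    timestamp_s = as.numeric(tapply(r$timestamp_s, visit, mean)),
    chamber_id = as.integer(tapply(r$chamber_id, visit, function(x) x[1])),
    flow_mol_s = as.numeric(tapply(r$flow_mol_s, visit, mean)),
    delta_co2_umol_mol = as.numeric(tapply(r$delta_co2_umol_mol, visit, mean)),
    light_on = as.logical(tapply(r$light_on, visit, function(x)
      mean(x) >= 0.5))
  )
  out <- out[order(out$timestamp_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Net canopy CO2 flux from flow and CO2 differential
#'
#' Converts a chamber mass flow and a pre/post-chamber CO2 mole-fraction
#' difference into a ground-area-based net flux. `delta_co2` is signed so
#' that net uptake by the canopy is positive (light period) and respiration
#' is negative (dark period).
#'
#' @param flow Air mass flow through the chamber (mol s-1), > 0.
#' @param delta_co2 Uptake-signed CO2 differential (umol mol-1).
#' @param ground_area Chamber ground area (m2), > 0.
#' @return Net flux P_net (umol CO2 m-2 s-1); vectorized over all arguments.
#' @examples
#' net_flux(0.034, 25, 0.17) # 5 umol m-2 s-1
#' @export
net_flux <- function(flow, delta_co2, ground_area) {
  if (any(flow <= 0)) stop("flow must be positive")
  if (any(ground_area <= 0)) stop("ground_area must be positive")
  flow * delta_co2 / ground_area
}

#' Per-chamber net flux series from demultiplexed records
#'
#' @param records Demultiplexed chamber records (see [demultiplex_stream()]).
#' @param ground_area Chamber ground area (m2).
#' @return Data.frame `timestamp_s, chamber_id, pnet_umol_m2_s, light_on`
#'   with `ground_area` stored as an attribute.
#' @export
flux_series <- function(records, ground_area) {
  out <- data.frame(
    timestamp_s = records$timestamp_s,
    chamber_id = records$chamber_id,
    pnet_umol_m2_s = net_flux(records$flow_mol_s,
                              records$delta_co2_umol_mol, ground_area),
    light_on = records$light_on)
  attr(out, "ground_area") <- ground_area
  out
}

# Mask of timestamps falling inside a light/dark transition exclusion window.
# Transitions are lights-on (start of day) and lights-off (photoperiod_h into
# the day); day boundaries are defined by the lights-on event at t = 0 mod 1 d.
# pre_guard_s extends the window backwards so that a collapsed sampling window
# straddling the switch is also excluded.
.transition_mask <- function(t, photoperiod_h, exclusion_s, pre_guard_s) {
  tod <- t %% 86400
  off <- photoperiod_h * 3600
  (tod < exclusion_s) |
    (tod >= off - pre_guard_s & tod < off + exclusion_s) |
    (tod >= 86400 - pre_guard_s)
}

#' Daily light- and dark-period mean fluxes
#'
#' Averages a per-chamber net flux series over the light and dark periods of
#' each day (day boundaries at the lights-on event). Samples within a
#' configurable window after each light/dark switch are excluded as
#' non-steady-state, as are samples just before a switch (whose averaging
#' window could straddle it). Means are converted from umol m-2 s-1 to
#' mol m-2 h-1.
#'
#' @param flux A [flux_series()] data.frame.
#' @param conv A [carbon_conversion()] (supplies the photoperiod).
#' @param transition_exclusion_min Minutes excluded after each light/dark
#'   switch (default 10).
#' @param pre_guard_s Seconds excluded before each switch (default 70, one
#'   default multiplexer slot).
#' @param min_completeness Minimum fraction of expected samples for a day to
#'   be flagged complete (default 0.8).
#' @return Data.frame `day, chamber_id, pnet_light_mol_m2_h, rdark_mol_m2_h,
#'   n_light, n_dark, complete`. A day with samples in only one period raises
#'   an incomplete-day error.
#' @export
daily_period_means <- function(flux, conv = carbon_conversion(),
                               transition_exclusion_min = 10,
                               pre_guard_s = 70,
                               min_completeness = 0.8) {
  stopifnot(inherits(conv, "carbon_conversion"))
  excl <- .transition_mask(flux$timestamp_s, conv$photoperiod_h,
                           transition_exclusion_min * 60, pre_guard_s)
  f <- flux[!excl, , drop = FALSE]
  if (nrow(f) == 0) stop("no samples left after transition exclusion")
  day <- f$timestamp_s %/% 86400 + 1

  # expected per-period sample count from the observed revisit period
  cyc <- stats::median(diff(sort(unique(f$timestamp_s[f$chamber_id ==
                                                        f$chamber_id[1]]))))
  exp_light <- (conv$photoperiod_h * 3600 - transition_exclusion_min * 60 -
                  pre_guard_s) / cyc
  exp_dark <- (conv$dark_h * 3600 - transition_exclusion_min * 60 -
                 pre_guard_s) / cyc

  key <- interaction(day, f$chamber_id, drop = TRUE)
  agg <- function(vals, sel) tapply(vals[sel], key[sel], mean)
  cnt <- function(sel) tapply(sel, key, sum)

  light_mean <- agg(f$pnet_umol_m2_s, f$light_on)
  dark_mean <- agg(f$pnet_umol_m2_s, !f$light_on)
  n_light <- cnt(f$light_on)
  n_dark <- cnt(!f$light_on)

  lv <- levels(key)
  parts <- do.call(rbind, strsplit(lv, ".", fixed = TRUE))
  out <- data.frame(
    day = as.integer(parts[, 1]),
    chamber_id = as.integer(parts[, 2]),
    pnet_light_mol_m2_h = as.numeric(light_mean[lv]) * 3600 * 1e-6,
    rdark_mol_m2_h = as.numeric(dark_mean[lv]) * 3600 * 1e-6,
    n_light = as.integer(n_light[lv]),
    n_dark = as.integer(n_dark[lv]))
  if (any(out$n_light == 0 | out$n_dark == 0))
    stop("incomplete day: a day/chamber has no light or no dark samples")
  out$complete <- out$n_light >= min_completeness * exp_light &
    out$n_dark >= min_completeness * exp_dark
  out <- out[order(out$chamber_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Daily gross canopy photosynthesis
#'
#' `(P_net,light + |R_dark|) * photoperiod_h * ground_area * g_per_mol`,
#' assuming respiration in the light equals dark respiration (the standard
#' assumption in canopy photosynthesis work).
#'
#' @param p_net_light Mean light-period net flux (mol m-2 h-1).
#' @param r_dark Mean dark-period net flux (mol m-2 h-1, usually <= 0).
#' @param conv A [carbon_conversion()].
#' @return Gross photosynthesis (g dry mass d-1); vectorized.
#' @export
gross_photosynthesis <- function(p_net_light, r_dark,
                                 conv = carbon_conversion()) {
  stopifnot(inherits(conv, "carbon_conversion"))
  (p_net_light + abs(r_dark)) * conv$photoperiod_h * conv$ground_area_m2 *
    conv$g_per_mol_co2
}

#' Daily carbon gain
#'
#' `(P_net,light * photoperiod_h - |R_dark| * dark_h) * ground_area *
#' g_per_mol`: day-time net uptake minus night-time respiratory loss,
#' expressed as grams of dry mass per day.
#'
#' @inheritParams gross_photosynthesis
#' @return Daily carbon gain (g d-1); vectorized.
#' @export
daily_carbon_gain <- function(p_net_light, r_dark,
                              conv = carbon_conversion()) {
  stopifnot(inherits(conv, "carbon_conversion"))
  (p_net_light * conv$photoperiod_h - abs(r_dark) * conv$dark_h) *
    conv$ground_area_m2 * conv$g_per_mol_co2
}

#' Carbon use efficiency
#'
#' `CUE = DCG / P_gross`: the fraction of carbon fixed in gross
#' photosynthesis that is retained as biomass. At most 1 whenever dark
#' respiration is non-positive.
#'
#' @param dcg Daily carbon gain (g d-1).
#' @param p_gross Gross photosynthesis (g d-1), > 0.
#' @return Dimensionless CUE; vectorized.
#' @export
carbon_use_efficiency <- function(dcg, p_gross) {
  if (any(p_gross <= 0)) stop("CUE undefined: P_gross must be positive")
  dcg / p_gross
}

#' Daily canopy carbon summaries from a flux series
#'
#' Convenience wrapper: [daily_period_means()] followed by
#' [gross_photosynthesis()], [daily_carbon_gain()] and
#' [carbon_use_efficiency()].
#'
#' @inheritParams daily_period_means
#' @param ... Passed to [daily_period_means()].
#' @return The [daily_period_means()] data.frame with columns `pgross_g_d`,
#'   `dcg_g_d`, `cue` appended.
#' @export
daily_summaries <- function(flux, conv = carbon_conversion(), ...) {
  out <- daily_period_means(flux, conv, ...)
  out$pgross_g_d <- gross_photosynthesis(out$pnet_light_mol_m2_h,
                                         out$rdark_mol_m2_h, conv)
  out$dcg_g_d <- daily_carbon_gain(out$pnet_light_mol_m2_h,
                                   out$rdark_mol_m2_h, conv)
  out$cue <- carbon_use_efficiency(out$dcg_g_d, out$pgross_g_d)
  out
}

#' Predict harvest dry mass from cumulative daily carbon gain
#'
#' Sums a daily-carbon-gain series onto an initial dry mass. When a measured
#' harvest mass is supplied, also reports the prediction as a percentage of
#' the measurement (the mass-balance closure check for a gas-exchange run).
#'
#' @param dcg_g_d Numeric vector of daily carbon gain (g d-1), one entry per
#'   day of the experiment.
#' @param initial_dry_mass_g Dry mass at the start of the series (g).
#' @param measured_mass_g Optional measured harvest dry mass (g), > 0.
#' @return List with `predicted_g` and, when a measurement is given,
#'   `percent_of_measured`.
#' @export
predict_harvest_mass <- function(dcg_g_d, initial_dry_mass_g = 0,
                                 measured_mass_g = NULL) {
  predicted <- initial_dry_mass_g + sum(dcg_g_d)
  out <- list(predicted_g = predicted)
  if (!is.null(measured_mass_g)) {
    if (measured_mass_g <= 0) stop("measured_mass_g must be positive")
    out$percent_of_measured <- 100 * predicted / measured_mass_g
  }
  out
}
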