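#' Gross photosynthesis per mole of incident photons
#'
#' Converts daily gross photosynthesis from g d-1 to mol CO2 fixed per mol of
#' incident photons: divide by the grams-per-mole conversion, by the chamber
#' ground area, and by the daily light integral.
#'
#' @param p_gross_g_d Gross photosynthesis (g d-1).
#' @param conv A [carbon_conversion()].
#' @param dli Daily light integral at canopy level (mol m-2 d-1), > 0.
#' @return mol CO2 per mol incident photons; vectorized.
#' @export
pgross_per_incident_photon <- function(p_gross_g_d,
                                       conv = carbon_conversion(),
                                       dli) {
  stopifnot(inherits(conv, "carbon_conversion"))
  if (any(dli <= 0)) stop("daily light integral must be positive")
  p_gross_g_d / conv$g_per_mol_co2 / conv$ground_area_m2 / dli
}

#' Canopy quantum yield for CO2 fixation
#'
#' Moles of CO2 fixed in gross photosynthesis per mole of photons absorbed by
#' the canopy (400--750 nm): gross photosynthesis on an incident-photon basis
#' divided by the canopy photon-capture fraction.
#'
#' @param p_gross_incident Gross photosynthesis (mol CO2 per mol incident
#'   photons), see [pgross_per_incident_photon()].
#' @param capture Canopy photon capture fraction in (0, 1\].
#' @return Canopy quantum yield (mol CO2 per mol absorbed photons);
#'   vectorized.
#' @export
canopy_quantum_yield <- function(p_gross_incident, capture) {
  if (any(capture <= 0) || any(capture > 1))
    stop("capture must lie in (0, 1]")
  p_gross_incident / capture
}

#' Regress photosynthesis on canopy photon capture
#'
#' Ordinary least-squares fit of daily gross photosynthesis (or daily carbon
#' gain) on canopy photon capture. With a grouping factor, fits each group
#' and the pooled data, and reports the maximum pairwise relative difference
#' between group slopes as a descriptive common-slope diagnostic.
#'
#' @param x Capture fractions (must have nonzero variance), length >= 3.
#' @param y Response values (e.g. P_gross or DCG, g d-1).
#' @param group Optional factor splitting observations into treatments.
#' @return An object of class `capture_regression`: list with `pooled`
#'   (slope, intercept, r2, n, residual_sd), `by_group` (data.frame of
#'   per-group fits, when `group` given) and `max_slope_rel_diff`.
#' @export
regress_on_capture <- function(x, y, group = NULL) {
  if (length(x) < 3 || length(y) != length(x))
    stop("need >= 3 aligned (x, y) pairs")
  if (stats::var(x) == 0)
    stop("degenerate regression: capture values have zero variance")
  one_fit <- function(x, y) {
    fit <- stats::lm(y ~ x)
    s <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = s$r.squared, n = length(x), residual_sd = s$sigma)
  }
  out <- list(pooled = one_fit(x, y))
  if (!is.null(group)) {
    group <- as.factor(group)
    fits <- lapply(split(data.frame(x, y), group),
                   function(d) one_fit(d$x, d$y))
    out$by_group <- data.frame(
      group = names(fits),
      slope = vapply(fits, `[[`, numeric(1), "slope"),
      intercept = vapply(fits, `[[`, numeric(1), "intercept"),
      r2 = vapply(fits, `[[`, numeric(1), "r2"),
      n = vapply(fits, `[[`, numeric(1), "n"),
      row.names = NULL)
    sl <- out$by_group$slope
    out$max_slope_rel_diff <- (max(sl) - min(sl)) / mean(abs(sl))
  }
  class(out) <- "capture_regression"
  out
}

#' @export
print.capture_regression <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<capture_regression> pooled: slope %.4g, intercept %.4g, r2 %.3f, n %d\n",
              p$slope, p$intercept, p$r2, p$n))
  if (!is.null(x$by_group)) {
    print(x$by_group)
    cat(sprintf("max pairwise relative slope difference: %.3f\n",
                x$max_slope_rel_diff))
  }
  invisible(x)
}

#' Build daily quantum-yield records
#'
#' Joins per-day gas-exchange summaries with per-day capture fractions for
#' one chamber and computes gross photosynthesis per incident photon and
#' canopy quantum yield.
#'
#' @param summaries Output of [daily_summaries()] for one chamber.
#' @param capture Output of [capture_series()] for the same chamber.
#' @param conv A [carbon_conversion()].
#' @param dli Daily light integral (mol m-2 d-1).
#' @return Data.frame `day, chamber_id, p_gross_incident, capture_fraction,
#'   quantum_yield`.
#' @export
quantum_yield_records <- function(summaries, capture,
                                  conv = carbon_conversion(), dli) {
  m <- merge(summaries[, c("day", "chamber_id", "pgross_g_d")],
             capture[, c("day", "capture_fraction")], by = "day")
  if (nrow(m) == 0) stop("alignment error: no shared days")
  m$p_gross_incident <- pgross_per_incident_photon(m$pgross_g_d, conv, dli)
  m$quantum_yield <- canopy_quantum_yield(m$p_gross_incident,
                                          m$capture_fraction)
  m[, c("day", "chamber_id", "p_gross_incident", "capture_fraction",
        "quantum_yield")]
}

#' Per-treatment report of canopy gas exchange, capture, and quantum yield
#'
#' Assembles the complete per-treatment output of the pipeline: the daily
#' time series (gas exchange, cover, capture, quantum yield) and harvest-time
#' aggregates (mean quantum yield over post-seedling days, mean mature-plant
#' CUE over the final days, final cover and capture, and predicted vs
#' measured harvest mass). Serializable to JSON with [write_report_json()].
#'
#' @param summaries [daily_summaries()] rows for all chambers.
#' @param captures Named list of [capture_series()] data.frames, one per
#'   chamber id.
#' @param treatments Data.frame `chamber_id, treatment, dli` mapping chambers
#'   to treatment names and daily light integrals.
#' @param harvest Optional data.frame `chamber_id, measured_mass_g,
#'   initial_mass_g` for mass-balance closure.
#' @param conv A [carbon_conversion()].
#' @param qy_exclude_days Days after transfer excluded from the quantum-yield
#'   aggregate (default 7; seedling capture estimates are least reliable).
#' @param cue_window_d Final days averaged for mature-plant CUE (default 6).
#' @return An object of class `treatment_report`: list with one element per
#'   treatment, each containing `daily` (data.frame) and `harvest` (list of
#'   aggregates).
#' @export
treatment_report <- function(summaries, captures, treatments,
                             harvest = NULL, conv = carbon_conversion(),
                             qy_exclude_days = 7, cue_window_d = 6) {
  out <- list()
  for (i in seq_len(nrow(treatments))) {
    ch <- treatments$chamber_id[i]
    name <- treatments$treatment[i]
    dli <- treatments$dli[i]
    s <- summaries[summaries$chamber_id == ch, , drop = FALSE]
    cap <- captures[[as.character(ch)]]
    if (is.null(cap) || nrow(s) == 0)
      stop("alignment error: chamber ", ch, " missing summaries or capture")
    qy <- quantum_yield_records(s, cap, conv, dli)
    daily <- merge(merge(s, cap, by = "day"),
                   qy[, c("day", "p_gross_incident", "quantum_yield")],
                   by = "day")
    daily <- daily[order(daily$day), , drop = FALSE]

    last_day <- max(daily$day)
    qy_days <- daily$day > qy_exclude_days
    cue_days <- daily$day > last_day - cue_window_d
    hv <- list(
      mean_quantum_yield = mean(daily$quantum_yield[qy_days]),
      sd_quantum_yield = stats::sd(daily$quantum_yield[qy_days]),
      mean_cue_mature = mean(daily$cue[cue_days]),
      final_cover = daily$cover_fraction[daily$day == last_day],
      final_capture = daily$capture_fraction[daily$day == last_day],
      cumulative_dcg_g = sum(daily$dcg_g_d))
    if (!is.null(harvest)) {
      h <- harvest[harvest$chamber_id == ch, , drop = FALSE]
      if (nrow(h) == 1) {
        init <- if ("initial_mass_g" %in% names(h)) h$initial_mass_g else 0
        pm <- predict_harvest_mass(daily$dcg_g_d, init, h$measured_mass_g)
        hv$predicted_mass_g <- pm$predicted_g
        hv$predicted_pct_of_measured <- pm$percent_of_measured
      }
    }
    out[[name]] <- list(chamber_id = ch, treatment = name, dli = dli,
                        daily = daily, harvest = hv)
  }
  class(out) <- "treatment_report"
  out
}

#' Write a treatment report to JSON (with a flat CSV companion)
#'
#' @param report A [treatment_report()].
#' @param path Output JSON path.
#' @param csv_path Optional path for a flat CSV of the daily tables.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, csv_path = NULL) {
  payload <- list(treatments = lapply(unclass(report), function(tr) {
    list(treatment = tr$treatment, chamber_id = tr$chamber_id, dli = tr$dli,
         daily = tr$daily, harvest = tr$harvest)
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) {
    flat <- do.call(rbind, lapply(unclass(report), function(tr) {
      cbind(treatment = tr$treatment, tr$daily)
    }))
    utils::write.csv(flat, csv_path, row.names = FALSE)
  }
  invisible(path)
}
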