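#' Run the full canopy analysis pipeline on an experiment
#'
#' Executes every stage of the analysis on raw inputs: demultiplexes the
#' analyzer stream, computes per-chamber net flux series and daily carbon
#' metrics, estimates daily ground cover from the top-down images, builds
#' the photon-capture series with the Beer-Lambert multilayer correction,
#' computes canopy quantum yield, and assembles the per-treatment report and
#' the photosynthesis-vs-capture regression.
#'
#' @param stream Raw multiplexed record data.frame (see
#'   [demultiplex_stream()] for the column layout).
#' @param spectra Named list (by chamber id) of [spectral_distribution()]s.
#' @param absorptance Named list (by chamber id) of
#'   [absorptance_spectrum()]s.
#' @param images Either a named list (by chamber id) of per-day image arrays
#'   or file paths, or a data.frame `day, chamber_id, cover_fraction` of
#'   precomputed cover fractions.
#' @param harvest Data.frame `chamber_id, leaf_area_m2` plus optionally
#'   `measured_mass_g` and `initial_mass_g`.
#' @param schedule A [sampling_schedule()].
#' @param conv A [carbon_conversion()].
#' @param treatment_names Optional named character vector (by chamber id);
#'   defaults to `chamber <id>`.
#' @param window_discard_s,transition_exclusion_min,overlap_window_d,qy_exclude_days,cue_window_d
#'   Stage options; see [demultiplex_stream()], [daily_period_means()],
#'   [capture_series()] and [treatment_report()].
#' @return List with `summaries` (daily gas-exchange metrics, all chambers),
#'   `covers`, `captures` (named list of [capture_series()] frames),
#'   `report` (a [treatment_report()]) and `regression`
#'   (a [regress_on_capture()] of daily P_gross on capture, grouped by
#'   treatment).
#' @export
analyze_experiment <- function(stream, spectra, absorptance, images, harvest,
                               schedule, conv = carbon_conversion(),
                               treatment_names = NULL,
                               window_discard_s = 10,
                               transition_exclusion_min = 10,
                               overlap_window_d = 7,
                               qy_exclude_days = 7, cue_window_d = 6) {
  records <- demultiplex_stream(stream, schedule,
                                window_discard_s = window_discard_s)
  flux <- flux_series(records, conv$ground_area_m2)
  summaries <- daily_summaries(flux, conv,
                               transition_exclusion_min = transition_exclusion_min)

  chambers <- sort(unique(summaries$chamber_id))
  covers <- if (is.data.frame(images)) {
    images
  } else {
    do.call(rbind, lapply(chambers, function(ch) {
      imgs <- images[[as.character(ch)]]
      data.frame(day = seq_along(imgs), chamber_id = ch,
                 cover_fraction = vapply(imgs, ground_cover_fraction,
                                         numeric(1)))
    }))
  }

  captures <- list()
  for (ch in chambers) {
    cv <- covers[covers$chamber_id == ch, , drop = FALSE]
    h <- harvest[harvest$chamber_id == ch, , drop = FALSE]
    if (nrow(h) != 1) stop("harvest row missing for chamber ", ch)
    sp <- spectra[[as.character(ch)]]
    leaf <- absorptance[[as.character(ch)]]
    la <- leaf_photon_absorption(sp, leaf)
    captures[[as.character(ch)]] <- capture_series(
      cv$day, cv$cover_fraction, h$leaf_area_m2, la,
      chamber_area_m2 = conv$ground_area_m2,
      overlap_window_d = overlap_window_d)
  }

  if (is.null(treatment_names))
    treatment_names <- stats::setNames(paste("chamber", chambers),
                                       as.character(chambers))
  tr <- data.frame(
    chamber_id = chambers,
    treatment = unname(treatment_names[as.character(chambers)]),
    dli = vapply(chambers, function(ch) {
      daily_light_integral(
        integrate_photon_flux(spectra[[as.character(ch)]],
                              waveband(400, 750, "total")),
        conv$photoperiod_h)
    }, numeric(1)))

  report <- treatment_report(summaries, captures, tr,
                             harvest = if ("measured_mass_g" %in%
                                           names(harvest)) harvest,
                             conv = conv,
                             qy_exclude_days = qy_exclude_days,
                             cue_window_d = cue_window_d)

  merged <- do.call(rbind, lapply(unclass(report), function(x)
    cbind(treatment = x$treatment,
          x$daily[, c("day", "pgross_g_d", "capture_fraction")])))
  regression <- regress_on_capture(merged$capture_fraction,
                                   merged$pgross_g_d, merged$treatment)

  list(summaries = summaries, covers = covers, captures = captures,
       report = report, regression = regression)
}

#' Analyze an experiment directory
#'
#' Runs [analyze_experiment()] on the plain-file layout written by
#' [write_experiment()]: `spectrum_chamber<ID>.csv`,
#' `absorptance_chamber<ID>.csv`, `stream.csv`, `harvest.csv` and
#' `chamber<ID>_day<D>.png` images.
#'
#' @param dir Experiment directory.
#' @param sample_s,purge_s Multiplexer schedule (defaults 30 s / 40 s); the
#'   chamber count is taken from the spectrum files present.
#' @param ... Passed to [analyze_experiment()].
#' @return See [analyze_experiment()].
#' @export
analyze_directory <- function(dir, sample_s = 30, purge_s = 40, ...) {
  spec_files <- list.files(dir, "^spectrum_chamber[0-9]+\\.csv$")
  if (!length(spec_files)) stop("no spectrum_chamber*.csv files in ", dir)
  ids <- sort(as.integer(sub("spectrum_chamber([0-9]+)\\.csv", "\\1",
                             spec_files)))
  spectra <- absorptance <- images <- list()
  for (ch in ids) {
    key <- as.character(ch)
    spectra[[key]] <- read_spectrum_csv(
      file.path(dir, sprintf("spectrum_chamber%d.csv", ch)))
    absorptance[[key]] <- read_absorptance_csv(
      file.path(dir, sprintf("absorptance_chamber%d.csv", ch)))
    img_files <- list.files(dir, sprintf("^chamber%d_day[0-9]+\\.png$", ch))
    days <- sort(as.integer(sub(".*_day([0-9]+)\\.png", "\\1", img_files)))
    images[[key]] <- lapply(days, function(d)
      file.path(dir, sprintf("chamber%d_day%d.png", ch, d)))
  }
  stream <- read_stream_csv(file.path(dir, "stream.csv"))
  harvest <- utils::read.csv(file.path(dir, "harvest.csv"))
  nm <- if ("treatment" %in% names(harvest))
    stats::setNames(harvest$treatment, as.character(harvest$chamber_id))
  analyze_experiment(stream, spectra, absorptance, images, harvest,
                     schedule = sampling_schedule(length(ids), sample_s,
                                                  purge_s),
                     treatment_names = nm, ...)
}

#' Run the pipeline directly on a simulated experiment
#'
#' Convenience wrapper around [analyze_experiment()] for the output of
#' [simulate_experiment()].
#'
#' @param sim A `canopy_simulation`.
#' @param ... Stage options passed to [analyze_experiment()].
#' @return See [analyze_experiment()].
#' @export
analyze_simulation <- function(sim, ...) {
  stopifnot(inherits(sim, "canopy_simulation"))
  images <- if (!is.null(sim$images)) {
    sim$images
  } else {
    td <- sim$truth$daily
    data.frame(day = td$day, chamber_id = td$chamber_id,
               cover_fraction = td$cover)
  }
  analyze_experiment(
    sim$stream, sim$spectra, sim$absorptance, images, sim$harvest,
    schedule = sim$truth$schedule, conv = sim$truth$conv,
    treatment_names = stats::setNames(sim$treatments$treatment,
                                      as.character(sim$treatments$chamber_id)),
    ...)
}
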