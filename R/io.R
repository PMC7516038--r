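#' Read and write the package's plain-text interchange formats
#'
#' All files are UTF-8 comma-separated tables with a header row; lines
#' starting with `#` are treated as comments.
#'
#' * Spectrum CSV: `wavelength_nm,flux_umol_m2_s_nm`
#' * Absorptance CSV: `wavelength_nm,absorptance`
#' * Coefficient CSV: `wavelength_nm,sigma_r,sigma_fr`
#' * Raw stream CSV: `timestamp_s,chamber_id,flow_mol_s,delta_co2_umol_mol,light_on`
#' * Daily summary CSV:
#'   `day,chamber_id,pnet_light_mol_m2_h,rdark_mol_m2_h,pgross_g_d,dcg_g_d,cue`
#' * Cover/capture CSV: `day,chamber_id,cover_fraction,leaf_layers,capture_fraction`
#'
#' @param path File path.
#' @return The corresponding package object or data.frame.
#' @name canopyflux-io
NULL

.read_csv <- function(path, required) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' @rdname canopyflux-io
#' @export
read_spectrum_csv <- function(path) {
  df <- .read_csv(path, c("wavelength_nm", "flux_umol_m2_s_nm"))
  spectral_distribution(df$wavelength_nm, df$flux_umol_m2_s_nm)
}

#' @rdname canopyflux-io
#' @param spectrum A [spectral_distribution()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelength_nm,
               flux_umol_m2_s_nm = spectrum$flux_density),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname canopyflux-io
#' @export
read_absorptance_csv <- function(path) {
  df <- .read_csv(path, c("wavelength_nm", "absorptance"))
  absorptance_spectrum(df$wavelength_nm, df$absorptance)
}

#' @rdname canopyflux-io
#' @param leaf An [absorptance_spectrum()].
#' @export
write_absorptance_csv <- function(leaf, path) {
  utils::write.csv(
    data.frame(wavelength_nm = leaf$wavelength_nm,
               absorptance = leaf$absorptance),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname canopyflux-io
#' @export
read_coefficients_csv <- function(path) {
  df <- .read_csv(path, c("wavelength_nm", "sigma_r", "sigma_fr"))
  photoconversion_coefficients(df$wavelength_nm, df$sigma_r, df$sigma_fr)
}

#' @rdname canopyflux-io
#' @export
read_stream_csv <- function(path) {
  df <- .read_csv(path, c("timestamp_s", "chamber_id", "flow_mol_s",
                          "delta_co2_umol_mol", "light_on"))
  df$light_on <- as.logical(df$light_on)
  df
}

#' @rdname canopyflux-io
#' @param stream A raw stream data.frame (see Details).
#' @export
write_stream_csv <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}
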