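#' Spectral distribution of a light source
#'
#' Constructs a `spectral_distribution`: photon flux density per unit
#' wavelength on a strictly increasing wavelength grid. This is the container
#' used for LED treatment spectra throughout the package.
#'
#' @param wavelength_nm Strictly increasing numeric vector of wavelengths (nm)
#'   with at least two points, spanning at least 400--750 nm.
#' @param flux_density Photon flux density at each grid point
#'   (umol m-2 s-1 nm-1); all values must be non-negative.
#' @return An object of class `spectral_distribution` (a list with elements
#'   `wavelength_nm` and `flux_density`).
#' @examples
#' sd <- spectral_distribution(380:780, rep(1, 401))
#' integrate_photon_flux(sd, waveband(400, 500))
#' @export
spectral_distribution <- function(wavelength_nm, flux_density) {
  wavelength_nm <- as.numeric(wavelength_nm)
  flux_density <- as.numeric(flux_density)
  if (length(wavelength_nm) < 2L)
    stop("spectral grid needs at least 2 points")
  if (length(wavelength_nm) != length(flux_density))
    stop("wavelength_nm and flux_density must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(!is.finite(flux_density)) || any(flux_density < 0))
    stop("flux_density must be finite and non-negative")
  if (wavelength_nm[1] > 400 || wavelength_nm[length(wavelength_nm)] < 750)
    stop("spectral grid must span at least [400, 750] nm")
  structure(list(wavelength_nm = wavelength_nm, flux_density = flux_density),
            class = "spectral_distribution")
}

#' @export
print.spectral_distribution <- function(x, ...) {
  rng <- range(x$wavelength_nm)
  cat(sprintf(
    "<spectral_distribution> %d points, %.0f-%.0f nm, total 400-750 nm flux %.2f umol m-2 s-1\n",
    length(x$wavelength_nm), rng[1], rng[2],
    integrate_photon_flux(x, waveband(400, 750, "total"))))
  invisible(x)
}

#' Leaf absorptance spectrum
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param absorptance Dimensionless fraction of photons absorbed by a single
#'   leaf layer at each wavelength; all values in \[0, 1\].
#' @return An object of class `absorptance_spectrum`.
#' @export
absorptance_spectrum <- function(wavelength_nm, absorptance) {
  wavelength_nm <- as.numeric(wavelength_nm)
  absorptance <- as.numeric(absorptance)
  if (length(wavelength_nm) != length(absorptance))
    stop("wavelength_nm and absorptance must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(!is.finite(absorptance)) || any(absorptance < 0) || any(absorptance > 1))
    stop("absorptance must lie in [0, 1]")
  structure(list(wavelength_nm = wavelength_nm, absorptance = absorptance),
            class = "absorptance_spectrum")
}

#' Phytochrome photoconversion coefficients
#'
#' Relative photoconversion cross-sections of the red-absorbing (Pr) and
#' far-red-absorbing (Pfr) forms of phytochrome, on a wavelength grid. Used by
#' [compute_ppe()]. A synthetic coefficient table shaped like the published
#' phytochrome photochemistry literature ships with the package; see
#' [default_photoconversion_coefficients()].
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param sigma_r,sigma_fr Non-negative relative photoconversion
#'   cross-sections of Pr and Pfr at each grid point.
#' @return An object of class `photoconversion_coefficients`.
#' @export
photoconversion_coefficients <- function(wavelength_nm, sigma_r, sigma_fr) {
  wavelength_nm <- as.numeric(wavelength_nm)
  sigma_r <- as.numeric(sigma_r)
  sigma_fr <- as.numeric(sigma_fr)
  n <- length(wavelength_nm)
  if (length(sigma_r) != n || length(sigma_fr) != n)
    stop("coefficient vectors must match the wavelength grid")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(sigma_r < 0) || any(sigma_fr < 0))
    stop("photoconversion coefficients must be non-negative")
  structure(list(wavelength_nm = wavelength_nm, sigma_r = sigma_r,
                 sigma_fr = sigma_fr),
            class = "photoconversion_coefficients")
}

#' Waveband definition
#'
#' @param lo_nm,hi_nm Band edges in nm, `lo_nm < hi_nm`.
#' @param label Optional label; the conventional horticultural bands are
#'   blue (400--500), green (500--600), red (600--700) and far_red (700--750).
#' @return An object of class `waveband`.
#' @export
waveband <- function(lo_nm, hi_nm, label = NULL) {
  if (!is.numeric(lo_nm) || !is.numeric(hi_nm) || lo_nm >= hi_nm)
    stop("waveband requires lo_nm < hi_nm")
  if (is.null(label)) label <- sprintf("%g-%g nm", lo_nm, hi_nm)
  structure(list(lo_nm = lo_nm, hi_nm = hi_nm, label = label),
            class = "waveband")
}

#' Standard horticultural wavebands
#'
#' The contiguous partition blue \[400,500), green \[500,600),
#' red \[600,700), far-red \[700,750\] used for waveband fractions. With
#' trapezoidal integration the shared edges make the four band integrals sum
#' exactly to the 400--750 nm total.
#'
#' @return Named list of [waveband()] objects.
#' @export
standard_wavebands <- function() {
  list(blue    = waveband(400, 500, "blue"),
       green   = waveband(500, 600, "green"),
       red     = waveband(600, 700, "red"),
       far_red = waveband(700, 750, "far_red"))
}

# Trapezoidal integral of y over x restricted to [lo, hi]; y is linearly
# interpolated at the cut points so that adjacent bands tile exactly.
.trapz_band <- function(x, y, lo, hi) {
  if (lo < x[1] || hi > x[length(x)])
    stop("band [", lo, ", ", hi, "] outside the spectral grid range")
  keep <- x > lo & x < hi
  xs <- c(lo, x[keep], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[keep],
          stats::approx(x, y, xout = hi)$y)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

#' Integrate photon flux over a waveband
#'
#' Trapezoidal integral of spectral photon flux density over a band, with the
#' flux density linearly interpolated at the band edges.
#'
#' @param spectrum A [spectral_distribution()].
#' @param band A [waveband()] lying within the spectral grid range.
#' @return Photon flux in the band (umol m-2 s-1).
#' @export
integrate_photon_flux <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "spectral_distribution"),
            inherits(band, "waveband"))
  .trapz_band(spectrum$wavelength_nm, spectrum$flux_density,
              band$lo_nm, band$hi_nm)
}

#' Waveband fractions of total 400--750 nm photon flux
#'
#' Splits the 400--750 nm photon flux of a spectrum into the blue, green, red
#' and far-red fractions of [standard_wavebands()]. The four fractions sum to
#' one by construction.
#'
#' @param spectrum A [spectral_distribution()].
#' @return Named numeric vector `c(blue, green, red, far_red)`.
#' @export
waveband_fractions <- function(spectrum) {
  bands <- standard_wavebands()
  flux <- vapply(bands, function(b) integrate_photon_flux(spectrum, b),
                 numeric(1))
  total <- sum(flux)
  if (total <= 0) stop("waveband fractions undefined: zero total 400-750 nm flux")
  flux / total
}

#' Daily light integral
#'
#' @param total_ppfd Photon flux density (umol m-2 s-1), >= 0.
#' @param photoperiod_h Photoperiod (h), >= 0.
#' @return Daily light integral (mol m-2 d-1).
#' @examples
#' daily_light_integral(350, 14) # 17.64
#' @export
daily_light_integral <- function(total_ppfd, photoperiod_h) {
  if (any(total_ppfd < 0) || any(photoperiod_h < 0))
    stop("total_ppfd and photoperiod_h must be non-negative")
  total_ppfd * photoperiod_h * 3600 * 1e-6
}

# Interpolate (x, y) onto grid, holding nothing outside the table's range:
# rule = 2 extends the end values, appropriate for slowly varying absorptance
# and coefficient tables.
.interp_onto <- function(x, y, grid) {
  stats::approx(x, y, xout = grid, rule = 2)$y
}

#' Phytochrome photoequilibrium of a spectrum
#'
#' Estimates the phytochrome photoequilibrium (PPE), the fraction of the
#' phytochrome pool driven into the active far-red-absorbing Pfr form by a
#' light spectrum:
#' \deqn{PPE = \frac{\int N(\lambda)\,\sigma_r(\lambda)\,d\lambda}
#'                  {\int N(\lambda)\,[\sigma_r(\lambda)+\sigma_{fr}(\lambda)]\,d\lambda}}
#' where \eqn{N} is the photon flux density and \eqn{\sigma_r},
#' \eqn{\sigma_{fr}} the photoconversion cross-sections of the Pr and Pfr
#' forms. PPE is invariant to uniform rescaling of the spectrum.
#'
#' @param spectrum A [spectral_distribution()].
#' @param coeffs A [photoconversion_coefficients()] table; interpolated onto
#'   the spectrum grid.
#' @return PPE as a fraction in \[0, 1\].
#' @export
compute_ppe <- function(spectrum, coeffs = default_photoconversion_coefficients()) {
  stopifnot(inherits(spectrum, "spectral_distribution"),
            inherits(coeffs, "photoconversion_coefficients"))
  grid <- spectrum$wavelength_nm
  sr <- .interp_onto(coeffs$wavelength_nm, coeffs$sigma_r, grid)
  sfr <- .interp_onto(coeffs$wavelength_nm, coeffs$sigma_fr, grid)
  num <- .trapz_band(grid, spectrum$flux_density * sr, grid[1], grid[length(grid)])
  den <- .trapz_band(grid, spectrum$flux_density * (sr + sfr),
                     grid[1], grid[length(grid)])
  if (den <= 0) stop("PPE undefined: zero photoconversion-weighted flux")
  num / den
}

#' Spectrum-weighted single-layer leaf photon absorption
#'
#' Fraction of incident photons absorbed by one layer of leaf under a given
#' spectrum: the absorptance spectrum weighted by the incident photon flux
#' density over the spectrum's full grid range,
#' \eqn{\int N(\lambda) a(\lambda) d\lambda / \int N(\lambda) d\lambda}.
#'
#' @param spectrum A [spectral_distribution()].
#' @param leaf An [absorptance_spectrum()]; interpolated onto the spectrum
#'   grid.
#' @return Fraction in \[0, 1\] (mol absorbed per mol incident).
#' @export
leaf_photon_absorption <- function(spectrum, leaf) {
  stopifnot(inherits(spectrum, "spectral_distribution"),
            inherits(leaf, "absorptance_spectrum"))
  grid <- spectrum$wavelength_nm
  a <- .interp_onto(leaf$wavelength_nm, leaf$absorptance, grid)
  total <- .trapz_band(grid, spectrum$flux_density, grid[1], grid[length(grid)])
  if (total <= 0) stop("leaf photon absorption undefined: zero total flux")
  .trapz_band(grid, spectrum$flux_density * a, grid[1], grid[length(grid)]) / total
}

#' Bundled synthetic phytochrome photoconversion coefficient table
#'
#' Loads the packaged coefficient table. The table is synthetic: it is built
#' from smooth absorption-band shapes for the Pr form (red peak near 666 nm,
#' minor blue band) and the Pfr form (far-red peak near 730 nm with
#' substantial red overlap), scaled to reproduce the photoequilibria that
#' published coefficient sets give for narrow-band red/blue LED sources.
#' Users with a measured or published coefficient table can load their own
#' with [read_coefficients_csv()].
#'
#' @return A [photoconversion_coefficients()] object.
#' @export
default_photoconversion_coefficients <- function() {
  path <- system.file("extdata", "phytochrome_coefficients_synthetic.csv",
                      package = "canopyflux", mustWork = TRUE)
  read_coefficients_csv(path)
}
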