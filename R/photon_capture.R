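#' Fraction of canopy ground cover from a top-down image
#'
#' Classifies each pixel of a top-down canopy photograph as plant or
#' background and returns the green-pixel fraction of the region of interest.
#' The default classifier calls a pixel "plant" when its green channel
#' dominates both other channels and exceeds an absolute threshold:
#' `G > R & G > B & G > green_threshold`. The rule is deliberately simple and
#' swappable via `classifier`.
#'
#' @param image Either a numeric array `height x width x 3` with channel
#'   values in \[0, 1\] (as returned by [png::readPNG()]) or the path to a
#'   PNG file.
#' @param roi Optional integer vector `c(row0, row1, col0, col1)` delimiting
#'   the region of interest (inclusive); default is the whole image. The ROI
#'   should correspond to the chamber ground area.
#' @param green_threshold Absolute green-channel threshold (fraction of full
#'   scale), default 0.15.
#' @param classifier Optional function `(r, g, b) -> logical matrix`
#'   replacing the default rule.
#' @return Green-pixel fraction of the ROI, in \[0, 1\].
#' @export
ground_cover_fraction <- function(image, roi = NULL, green_threshold = 0.15,
                                  classifier = NULL) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("image must be an array with at least 3 channels")
  if (!is.null(roi)) {
    if (length(roi) != 4 || roi[1] > roi[2] || roi[3] > roi[4])
      stop("roi must be c(row0, row1, col0, col1) with row0 <= row1, col0 <= col1")
    image <- image[roi[1]:roi[2], roi[3]:roi[4], , drop = FALSE]
  }
  if (length(image[, , 1]) == 0) stop("empty region of interest")
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  plant <- if (is.null(classifier)) {
    g > r & g > b & g > green_threshold
  } else {
    classifier(r, g, b)
  }
  mean(plant)
}

#' Fit an exponential growth curve to leaf-area observations
#'
#' Ordinary least squares of `log(area)` on time, i.e. the model
#' `A(t) = A0 * exp(r * t)`. Used to interpolate total canopy leaf area
#' between the young-canopy phase (when projected area equals total area)
#' and the harvest measurement.
#'
#' @param times Observation times (days), length >= 2.
#' @param areas Leaf areas (m2), all > 0.
#' @return List with `A0`, `r`, and `predict(t)`, a function evaluating the
#'   fitted curve.
#' @export
fit_exponential_growth <- function(times, areas) {
  if (length(times) < 2 || length(areas) != length(times))
    stop("need >= 2 (time, area) pairs")
  if (any(areas <= 0)) stop("areas must be positive for an exponential fit")
  fit <- stats::lm(log(areas) ~ times)
  a0 <- exp(unname(stats::coef(fit)[1]))
  r <- unname(stats::coef(fit)[2])
  list(A0 = a0, r = r,
       predict = function(t) a0 * exp(r * t))
}

#' Number of leaf layers within the covered area
#'
#' Total canopy leaf area divided by projected (covered) ground area, floored
#' at 1: canopies that have not yet overlapped are treated as a single layer.
#'
#' @param total_leaf_area Total canopy leaf area (m2).
#' @param projected_area Projected canopy ground cover (m2), > 0.
#' @return Leaf layers (dimensionless >= 1); vectorized.
#' @export
leaf_layers <- function(total_leaf_area, projected_area) {
  if (any(projected_area <= 0)) stop("projected_area must be positive")
  pmax(1, total_leaf_area / projected_area)
}

#' Beer-Lambert extinction coefficient from single-layer absorption
#'
#' Inverts the Beer-Lambert law at one leaf layer: `k = -log(1 - a)`, where
#' `a` is the fraction of photons absorbed by a single layer of leaves.
#'
#' @param single_layer_absorption Fraction in (0, 1).
#' @return Extinction coefficient k (> 0); vectorized.
#' @examples
#' extinction_coefficient(0.798) # ~1.6
#' @export
extinction_coefficient <- function(single_layer_absorption) {
  if (any(single_layer_absorption <= 0) || any(single_layer_absorption >= 1))
    stop("single-layer absorption must lie strictly in (0, 1)")
  -log(1 - single_layer_absorption)
}

#' Beer-Lambert canopy photon absorption within the covered area
#'
#' `1 - exp(-k * layers)`: the fraction of photons absorbed by `layers`
#' overlapping leaf layers with extinction coefficient `k`.
#'
#' @param k Extinction coefficient, > 0.
#' @param layers Leaf layers (LAI within the covered area), >= 0.
#' @return Absorbed fraction in \[0, 1); vectorized.
#' @examples
#' beer_lambert_absorption(1.6, 2)   # ~0.959
#' beer_lambert_absorption(1.6, 2.6) # ~0.984
#' @export
beer_lambert_absorption <- function(k, layers) {
  if (any(k <= 0)) stop("extinction coefficient must be positive")
  if (any(layers < 0)) stop("layers must be non-negative")
  1 - exp(-k * layers)
}

#' Canopy photon capture from ground cover and within-cover absorption
#'
#' Canopy photon capture (mol absorbed per mol incident over the whole
#' chamber floor) is the covered fraction times the absorbed fraction within
#' the covered area. For a single-layer canopy the latter is the
#' spectrum-weighted single-leaf absorption; once leaves overlap it is the
#' Beer-Lambert value.
#'
#' @param cover Ground-cover fraction in \[0, 1\].
#' @param within_cover_absorption Absorbed fraction within the covered area,
#'   in \[0, 1\].
#' @return Capture fraction in \[0, 1\]; vectorized.
#' @export
canopy_capture <- function(cover, within_cover_absorption) {
  if (any(cover < 0 | cover > 1))
    stop("cover must lie in [0, 1]")
  if (any(within_cover_absorption < 0 | within_cover_absorption > 1))
    stop("within_cover_absorption must lie in [0, 1]")
  cover * within_cover_absorption
}

#' Daily canopy photon capture series from cover and harvest data
#'
#' Builds the per-day capture series for one chamber from daily ground-cover
#' fractions, the harvest leaf area, and the spectrum-weighted single-leaf
#' photon absorption of that chamber's light treatment:
#'
#' 1. projected area = cover x chamber ground area;
#' 2. total leaf area is interpolated with [fit_exponential_growth()] fitted
#'    to the young-canopy projected areas (days up to
#'    `last day - overlap_window_d`, when projected area is a good estimate
#'    of total area) plus the measured harvest total;
#' 3. leaf layers = interpolated total / projected, floored at 1; the
#'    Beer-Lambert correction applies on days where the interpolated total
#'    exceeds the projected area;
#' 4. capture = cover x `(1 - exp(-k * layers))` with
#'    `k = -log(1 - leaf_absorption)`.
#'
#' @param days Day indices (1-based).
#' @param cover Ground-cover fractions, same length as `days`.
#' @param harvest_leaf_area_m2 Total canopy leaf area at the final day (m2).
#' @param leaf_absorption Spectrum-weighted single-layer leaf photon
#'   absorption for the treatment (fraction in (0,1)); see
#'   [leaf_photon_absorption()].
#' @param chamber_area_m2 Chamber ground area (m2), default 0.17.
#' @param overlap_window_d Days before harvest during which leaves may
#'   overlap; earlier days anchor the exponential fit (default 7).
#' @return Data.frame `day, cover_fraction, projected_area_m2,
#'   total_leaf_area_m2, leaf_layers, capture_fraction` with the extinction
#'   coefficient as attribute `k`.
#' @export
capture_series <- function(days, cover, harvest_leaf_area_m2,
                           leaf_absorption, chamber_area_m2 = 0.17,
                           overlap_window_d = 7) {
  if (length(days) != length(cover)) stop("days and cover lengths differ")
  if (any(cover <= 0)) stop("cover must be positive to estimate leaf area")
  projected <- cover * chamber_area_m2
  young <- days <= max(days) - overlap_window_d
  if (!any(young)) young <- days == min(days)
  fit <- fit_exponential_growth(c(days[young], max(days)),
                                c(projected[young], harvest_leaf_area_m2))
  total <- pmin(fit$predict(days), harvest_leaf_area_m2)
  layers <- leaf_layers(total, projected)
  k <- extinction_coefficient(leaf_absorption)
  absorbed <- beer_lambert_absorption(k, layers)
  out <- data.frame(day = days, cover_fraction = cover,
                    projected_area_m2 = projected,
                    total_leaf_area_m2 = total,
                    leaf_layers = layers,
                    capture_fraction = canopy_capture(cover, absorbed))
  attr(out, "k") <- k
  out
}
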