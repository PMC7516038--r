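test_that("ground cover equals the green-pixel fraction of the ROI", {
  all_green <- array(rep(c(0.1, 0.7, 0.1), each = 16), c(4, 4, 3))
  expect_equal(ground_cover_fraction(all_green), 1)

  soil <- array(rep(c(0.45, 0.35, 0.3), each = 16), c(4, 4, 3))
  expect_equal(ground_cover_fraction(soil), 0)

  # dark pixels below the absolute green threshold are not plant
  dark <- array(rep(c(0.05, 0.1, 0.05), each = 16), c(4, 4, 3))
  expect_equal(ground_cover_fraction(dark), 0)

  img <- disk_image()
  truth <- attr(img, "true_fraction")
  expect_equal(truth, 0.375, tolerance = 0.03)
  expect_equal(ground_cover_fraction(img), truth)

  # ROI restriction: the center of the disk is fully green
  expect_equal(ground_cover_fraction(img, roi = c(45, 55, 45, 55)), 1)
  expect_error(ground_cover_fraction(img, roi = c(5, 2, 1, 4)), "roi")

  # a custom classifier is honoured
  expect_equal(ground_cover_fraction(img, classifier = function(r, g, b)
    r > -1), 1)
})

test_that("round-tripping an image through PNG preserves the cover estimate", {
  img <- render_canopy_image(0.4, size = 80, seed = 3)
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path))
  png::writePNG(img, path)
  expect_equal(ground_cover_fraction(path), ground_cover_fraction(img),
               tolerance = 0.005)
})

test_that("exponential growth fitting recovers known parameters", {
  t <- 0:10
  a <- 0.01 * exp(0.2 * t)
  fit <- fit_exponential_growth(t, a)
  expect_equal(fit$A0, 0.01, tolerance = 1e-10)
  expect_equal(fit$r, 0.2, tolerance = 1e-10)
  expect_equal(fit$predict(7.5), 0.01 * exp(1.5), tolerance = 1e-10)

  # two points: the exact interpolating exponential
  fit2 <- fit_exponential_growth(c(2, 6), c(0.02, 0.16))
  expect_equal(fit2$predict(2), 0.02, tolerance = 1e-12)
  expect_equal(fit2$predict(6), 0.16, tolerance = 1e-12)

  # 5% lognormal noise, n = 12: growth rate within 15%
  set.seed(19)
  t12 <- 0:11
  noisy <- 0.01 * exp(0.2 * t12) * exp(stats::rnorm(12, 0, 0.05))
  expect_equal(fit_exponential_growth(t12, noisy)$r, 0.2, tolerance = 0.15)

  expect_error(fit_exponential_growth(1, 0.1), "pairs")
  expect_error(fit_exponential_growth(c(1, 2), c(0.1, -0.1)), "positive")
})

test_that("leaf layers are total over projected area, floored at one", {
  expect_equal(leaf_layers(0.1, 0.1), 1)
  expect_equal(leaf_layers(0.2, 0.1), 2)
  expect_equal(leaf_layers(0.05, 0.1), 1)  # pre-overlap canopy
  expect_equal(leaf_layers(0.4423, 0.17), 2.6, tolerance = 1e-2)
  expect_error(leaf_layers(0.1, 0), "positive")
})

test_that("extinction coefficient and multilayer absorption match the worked example", {
  expect_equal(signif(extinction_coefficient(0.798), 2), 1.6)
  expect_equal(extinction_coefficient(1 - exp(-1)), 1)
  expect_equal(extinction_coefficient(0.927), -log(0.073))
  expect_equal(round(beer_lambert_absorption(1.6, 2), 3), 0.959)
  expect_equal(round(beer_lambert_absorption(1.6, 2.6), 3), 0.984)
  expect_equal(beer_lambert_absorption(1.6, 0), 0)
  expect_error(extinction_coefficient(1), "\\(0, 1\\)")
  expect_error(extinction_coefficient(0), "\\(0, 1\\)")
  expect_error(beer_lambert_absorption(-1, 2), "positive")
  expect_error(beer_lambert_absorption(1.6, -1), "non-negative")
})

test_that("extinction and absorption are exact inverses at one layer", {
  for (a in seq(0.05, 0.95, by = 0.05)) {
    expect_equal(beer_lambert_absorption(extinction_coefficient(a), 1), a,
                 tolerance = 1e-12)
  }
})

test_that("canopy capture is the cover-absorption product with monotone bounds", {
  expect_equal(canopy_capture(1, 0.8), 0.8)
  expect_equal(canopy_capture(0, 0.8), 0)
  expect_equal(canopy_capture(0.5, 0.798), 0.399)
  expect_error(canopy_capture(1.2, 0.5), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:25) {
    cover <- stats::runif(1); a <- stats::runif(1)
    k <- stats::runif(1, 0.5, 3); layers <- stats::runif(1, 1, 4)
    cap <- canopy_capture(cover, beer_lambert_absorption(k, layers))
    expect_lte(cap, cover)
    expect_lte(cap, 1)
    # nondecreasing in cover, absorption, and layers
    expect_gte(canopy_capture(min(1, cover + 0.1),
                              beer_lambert_absorption(k, layers)), cap)
    expect_gte(canopy_capture(cover, beer_lambert_absorption(k + 0.2, layers)),
               cap)
    expect_gte(canopy_capture(cover, beer_lambert_absorption(k, layers + 0.5)),
               cap)
  }
})

test_that("the capture series reduces to cover x leaf absorption pre-overlap", {
  days <- 1:12
  cover <- 0.02 * exp(0.25 * (days - 1))
  a <- 0.9
  # harvest total equal to the final projected area: no overlap anywhere
  cs <- capture_series(days, cover, harvest_leaf_area_m2 = 0.17 * cover[12],
                       leaf_absorption = a, chamber_area_m2 = 0.17)
  expect_equal(cs$leaf_layers, rep(1, 12), tolerance = 1e-9)
  expect_equal(cs$capture_fraction, cover * a, tolerance = 1e-9)
  expect_equal(attr(cs, "k"), -log(1 - a))
})

test_that("the capture series applies the multilayer correction after overlap", {
  days <- 1:14
  # projected cover saturates while the harvest area implies 2 layers
  cover <- pmin(0.9, 0.05 * exp(0.3 * (days - 1)))
  harvest_area <- 2 * 0.9 * 0.17
  cs <- capture_series(days, cover, harvest_area, leaf_absorption = 0.798)
  expect_gt(cs$leaf_layers[14], 1.5)
  expect_lte(max(cs$capture_fraction), 1)
  # capture on overlapped days exceeds the single-layer estimate
  single <- cover[14] * 0.798
  expect_gt(cs$capture_fraction[14], single)
})
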