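test_that("average emission wavelength matches hand-computed weighted means", {
  # point mass: all intensity at one wavelength
  sp <- emission_spectrum(c(300, 340, 400), c(0, 5, 0))
  expect_equal(avg_emission_wavelength(sp), 340)
  # uniform intensities on the standard 300-400 nm grid: grid centre
  sp <- emission_spectrum(300:400, rep(1, 101))
  expect_equal(avg_emission_wavelength(sp), 350)
  # two-point spectrum, hand arithmetic (320 + 3*360)/4
  sp <- emission_spectrum(c(320, 360), c(1, 3))
  expect_equal(avg_emission_wavelength(sp), 350)
})

test_that("average emission wavelength is scale invariant and grid bounded", {
  set.seed(BASE_SEED)
  for (i in 1:25) {
    wl <- sort(runif(sample(5:80, 1), 300, 400))
    wl <- wl[!duplicated(wl)]
    if (length(wl) < 2) next
    I <- runif(length(wl))
    sp <- emission_spectrum(wl, I)
    lam <- avg_emission_wavelength(sp)
    expect_gte(lam, min(wl))
    expect_lte(lam, max(wl))
    c_scale <- runif(1, 0.01, 100)
    sp2 <- emission_spectrum(wl, c_scale * I)
    expect_equal(avg_emission_wavelength(sp2), lam)
  }
})

test_that("degenerate and malformed spectra are rejected", {
  expect_error(avg_emission_wavelength(emission_spectrum(c(300, 301),
                                                         c(0, 0))),
               "degenerate")
  expect_error(emission_spectrum(c(300, 300), c(1, 1)), "increasing")
  expect_error(emission_spectrum(c(300, 301), c(1, -1)), "non-negative")
  expect_error(emission_spectrum(300:302, c(1, 1)), "same length")
})

test_that("spectra_to_curve assembles sorted curves from spectra", {
  mk <- function(value, centre) {
    emission_spectrum(300:400, exp(-(300:400 - centre)^2 / 50),
                      condition = list(axis_kind = "pH", value = value,
                                       excitation_nm = 280))
  }
  # constant input -> flat curve (and sorted by condition)
  cv <- spectra_to_curve(list(mk(11, 340), mk(3, 340), mk(7, 340)))
  expect_equal(cv$x, c(3, 7, 11))
  expect_equal(diff(cv$y), c(0, 0), tolerance = 1e-12)
  # point mass moving 330 -> 350 gives a monotone increasing curve
  cv <- spectra_to_curve(lapply(1:5, function(i) {
    emission_spectrum(300:400,
                      as.numeric(300:400 == 326 + 4 * i),
                      condition = list(axis_kind = "denaturant",
                                       value = i, excitation_nm = 280))
  }))
  expect_true(all(diff(cv$y) > 0))
})

test_that("spectra_to_curve reproduces a known unfolded-fraction schedule", {
  fr <- c(0, 0.2, 0.5, 0.8, 1)
  sps <- gen_spectrum_series(fr, conditions = seq(0, 4, 1),
                             folded_max = 330, unfolded_max = 350,
                             bandwidth = 10, grid = 300:400)
  cv <- spectra_to_curve(sps)
  # independent expectation: centroid of the discretized two-band mix
  grid <- 300:400
  band <- function(mu) exp(-(grid - mu)^2 / (2 * 10^2))
  expected <- vapply(fr, function(f) {
    I <- (1 - f) * band(330) + f * band(350)
    sum(grid * I) / sum(I)
  }, numeric(1))
  expect_equal(cv$y, expected, tolerance = 1e-9)
})

test_that("spectra_to_curve validates its inputs", {
  a <- emission_spectrum(300:400, rep(1, 101),
                         condition = list(axis_kind = "pH", value = 3))
  b <- emission_spectrum(300:400, rep(1, 101),
                         condition = list(axis_kind = "denaturant",
                                          value = 1))
  expect_error(spectra_to_curve(list(a, b)), "mixed axis kinds")
  expect_error(spectra_to_curve(list(a)), "at least 2")
  # off-grid intensity read warns beyond 0.5 nm
  coarse <- emission_spectrum(seq(300, 400, 2), rep(1, 51))
  expect_warning(intensity_at(coarse, 341), "off the grid")
  expect_silent(intensity_at(a, 340.3))
})

test_that("normalization to the lowest condition divides by the reference", {
  cv <- denaturation_curve(c(2, 7, 12), c(2, 4, 6), axis_kind = "pH")
  nv <- normalize_to_lowest_condition(cv)
  expect_equal(nv$y, c(1, 2, 3))
  expect_identical(nv$y[which.min(nv$x)], 1)
  # idempotent
  expect_equal(normalize_to_lowest_condition(nv)$y, nv$y)
  # sign preserving for negative ellipticities
  cv <- denaturation_curve(c(2, 7), c(-10, -5), axis_kind = "pH",
                           probe = "far-UV CD")
  expect_equal(normalize_to_lowest_condition(cv)$y, c(1, 0.5))
  # zero reference rejected
  cv <- denaturation_curve(c(2, 7), c(0, 5), axis_kind = "pH")
  expect_error(normalize_to_lowest_condition(cv), "zero")
})

test_that("curve ingest sorts, deduplicates and rejects conflicts", {
  cv <- denaturation_curve(c(3, 1, 2, 1), c(30, 10, 20, 10))
  expect_equal(cv$x, 1:3)
  expect_equal(cv$y, c(10, 20, 30))
  expect_error(denaturation_curve(c(1, 1, 2), c(10, 11, 20)),
               "duplicate")
})
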