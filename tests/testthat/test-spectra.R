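test_that("spectrum CSV round-trips, sorts, and rejects bad input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "wavelength_nm,value",
               "500,0.0", "600,1.0", "700,0.0"), p)
  s <- read_spectrum(p, "emission")
  expect_s3_class(s, "qdfret_spectrum")
  expect_length(s$wavelengths, 3)

  # descending input sorts to the same spectrum
  writeLines(c("700,0.0", "600,1.0", "500,0.0"), p)
  s2 <- read_spectrum(p, "emission")
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$values, s$values)

  writeLines(c("500,0.0", "600,1.0", "600,0.5", "700,0.0"), p)
  expect_error(read_spectrum(p, "emission"), "duplicate")

  writeLines(c("500,0.0", "600,oops", "700,0.0"), p)
  expect_error(read_spectrum(p, "emission"), "line 2")

  expect_error(spectrum_curve(c(500, 600), c(-1, 2), "absorbance"),
               "negative")
  expect_error(spectrum_curve(500, 1), "at least 2")
})

test_that("area_normalize scales, is idempotent, and matches dense quadrature", {
  wl <- seq(500, 600, by = 1)
  tri <- spectrum_curve(wl, 2 * pmax(0, 1 - abs(wl - 550) / 50), "emission")
  nrm <- area_normalize(tri)
  expect_equal(spectrum_area(nrm), 1, tolerance = 1e-9)
  expect_equal(nrm$values, tri$values / spectrum_area(tri))

  again <- area_normalize(nrm)
  expect_equal(again$values, nrm$values, tolerance = 1e-9)

  expect_error(area_normalize(spectrum_curve(wl, rep(0, length(wl)),
                                             "emission")),
               "integral")

  # Gaussian band: module trapezoid vs 1e6-point quadrature oracle
  g <- make_gaussian_spectrum(600, 30, peak = 7.3, wl = seq(450, 750, 0.5))
  dense <- seq(450, 750, length.out = 1e6 + 1)
  area_oracle <- pracma::trapz(
    dense, 7.3 * exp(-(dense - 600)^2 / (2 * gauss_sd(30)^2)))
  expect_equal(spectrum_area(g), area_oracle, tolerance = 1e-6)
})

test_that("overlap integral matches the dense quadrature oracle and the delta limit", {
  wl <- seq(450, 800, by = 0.25)
  d <- make_gaussian_spectrum(600, 30, wl = wl)
  a <- make_gaussian_spectrum(650, 40, peak = 2.39e5, wl = wl,
                              kind = "absorptivity")
  J <- overlap_integral(d, a)
  J_oracle <- oracle_overlap_gaussian(600, 30, 650, 40, 2.39e5, 450, 800)
  expect_equal(as.numeric(J), J_oracle, tolerance = 1e-3)

  # bilinearity: scaling the absorptivity scales J exactly
  a5 <- spectrum_curve(a$wavelengths, 5 * a$values, "absorptivity")
  expect_equal(as.numeric(overlap_integral(d, a5)), 5 * as.numeric(J),
               tolerance = 1e-12)

  # disjoint supports give zero with a warning
  d_lo <- make_gaussian_spectrum(470, 10, wl = seq(440, 500, 0.5))
  a_hi <- make_gaussian_spectrum(650, 10, peak = 1e5, kind = "absorptivity",
                                 wl = seq(610, 700, 0.5))
  expect_warning(J0 <- overlap_integral(d_lo, a_hi), "disjoint")
  expect_identical(as.numeric(J0), 0)

  # shrinking donor bandwidth against flat absorptivity -> eps * 600^4
  flat <- spectrum_curve(seq(400, 800, 1), rep(1e5, 401), "absorptivity")
  Js <- vapply(c(8, 4, 2, 1), function(fw) {
    grid <- seq(600 - 6 * fw, 600 + 6 * fw, length.out = 2001)
    as.numeric(overlap_integral(
      make_gaussian_spectrum(600, fw, wl = grid), flat))
  }, numeric(1))
  target <- 1e5 * 600^4  # 1.296e16
  errs <- abs(Js - target) / target
  expect_lt(errs[4], 1e-3)
  expect_true(all(diff(errs) < 0))  # converges monotonically to the limit
})

test_that("Forster distance follows the sixth-root law and frozen example", {
  expect_identical(forster_distance(0, 0.5), 0)
  # hand evaluation: 0.0211 * (2/3 * 0.3 * 1.35^-4 * 1e15)^(1/6)
  expect_equal(forster_distance(1e15, 0.3), 4.177325, tolerance = 1e-6)
  r1 <- forster_distance(2.7e14, 0.62)
  expect_equal(forster_distance(64 * 2.7e14, 0.62), 2 * r1,
               tolerance = 1e-12)
  expect_error(forster_distance(-1, 0.5), ">= 0")
  expect_error(forster_distance(1e15, 0), "quantum_yield")
  expect_error(forster_distance(1e15, 1.2), "quantum_yield")
})

test_that("Beer-Lambert concentrations reproduce the QD worked values", {
  expect_equal(beer_lambert_concentration(0.3, 3e6), 1e-7)   # 100 nM
  expect_equal(beer_lambert_concentration(0.29, 2.9e7), 1e-8) # 10 nM
  expect_identical(beer_lambert_concentration(0, 3e6), 0)
  expect_error(beer_lambert_concentration(0.3, 0), "extinction")
  expect_error(beer_lambert_concentration(0.3, 3e6, 0), "path_length")
})

test_that("relative quantum yield follows the single-point relative method", {
  expect_equal(relative_quantum_yield(100, 0.1, 100, 0.1, 0.92, 1.36, 1.36),
               0.92)
  expect_equal(relative_quantum_yield(50, 0.1, 100, 0.1, 0.92, 1.36, 1.36),
               0.46)
  # intensity ratio 1.3, absorbance ratio 0.8, sample absorbance above
  # the recommended 0.2 ceiling: warn but report the value
  expect_warning(
    qy <- relative_quantum_yield(130, 0.25, 100, 0.2, 0.92, 1.36, 1.36),
    "inner-filter")
  expect_equal(qy, 0.92 * 1.3 * 0.8, tolerance = 1e-12)
  expect_error(relative_quantum_yield(100, 0.1, 0, 0.1), "intensity")
  expect_warning(relative_quantum_yield(90, 0.3, 100, 0.3, 0.92, 1.36, 1.36),
                 "inner-filter")
})

test_that("absorbance unmixing recovers known mixtures", {
  wl <- seq(400, 800, by = 1)
  qd <- make_gaussian_spectrum(610, 35, peak = 3e5, wl = wl,
                               kind = "absorptivity")
  qd <- spectrum_curve(wl, qd$values + 2e5 * (350 / wl)^3, "absorptivity")
  dye <- make_gaussian_spectrum(650, 40, peak = 2.4e5, wl = wl,
                                kind = "absorptivity")
  comps <- list(QD = qd, dye = dye)

  # pure QD -> dye/QD ratio 0
  pure <- spectrum_curve(wl, 1e-7 * qd$values, "absorbance")
  u0 <- unmix_absorbance(pure, comps)
  expect_equal(unname(u0$ratios["dye", "QD"]), 0, tolerance = 1e-9)

  # exact self-consistency at 50 nM QD + 150 nM dye
  mix <- spectrum_curve(wl, 5e-8 * qd$values + 1.5e-7 * dye$values,
                        "absorbance")
  u <- unmix_absorbance(mix, comps)
  expect_equal(unname(u$concentrations), c(5e-8, 1.5e-7), tolerance = 1e-6)
  expect_equal(unname(u$ratios["dye", "QD"]), 3, tolerance = 1e-6)
  expect_lt(u$residual_norm, 1e-9 * max(mix$values) * length(wl))

  # collinear components are refused by name
  expect_error(
    unmix_absorbance(mix, list(
      QD = qd, QD2 = spectrum_curve(wl, 2 * qd$values, "absorptivity"))),
    "QD2")

  # 1% peak noise, 100 replicates: mean recovered ratio within 2% of 3
  sd_noise <- 0.01 * max(mix$values)
  set.seed(11)
  ratios <- replicate(100, {
    noisy <- spectrum_curve(
      wl, pmax(mix$values + rnorm(length(wl), 0, sd_noise), 0),
      "absorbance")
    unname(unmix_absorbance(noisy, comps)$ratios["dye", "QD"])
  })
  expect_equal(mean(ratios), 3, tolerance = 0.02)
})
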