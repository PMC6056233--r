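test_that("spectrum constructor enforces its invariants", {
  s <- spectrum(c(400, 500), c(0, 1), kind = "emission")
  expect_length(s$wavelengths_nm, 2L)
  # unsorted input is sorted; duplicates rejected
  s2 <- spectrum(c(500, 400), c(1, 0), kind = "emission")
  expect_equal(s2$wavelengths_nm, c(400, 500))
  expect_error(spectrum(c(400, 450, 450), c(1, 2, 3), kind = "emission"),
               "duplicate")
  expect_error(spectrum(c(400, 500), c(1, -5), kind = "absorption"),
               "negative absorption")
  # emission baseline noise is clipped, with a message
  expect_message(s3 <- spectrum(c(400, 500), c(-0.1, 1), kind = "emission"),
                 "clipped")
  expect_equal(s3$values, c(0, 1))
  expect_error(spectrum(c(400, 500), c(1, NA), kind = "emission"),
               "non-finite")
})

test_that("spectrum files round-trip value-for-value and reject bad rows", {
  cfg <- generator_config(seed = 11)
  sp <- make_spectra(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp$donor_emission, path)
  back <- read_spectrum(path, kind = "emission")
  expect_identical(back$wavelengths_nm, sp$donor_emission$wavelengths_nm)
  expect_identical(back$values, sp$donor_emission$values)

  # minimal two-row table, headerless, and the tab dialect
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "400\t0.0", "500\t1.0"), p2)
  s <- read_spectrum(p2, kind = "emission")
  expect_equal(s$wavelengths_nm, c(400, 500))
  expect_equal(s$values, c(0, 1))

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("450,1.0", "450,2.0"), p3)
  expect_error(read_spectrum(p3, kind = "emission"), "duplicate wavelength")

  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("400,1.0", "oops"), p4)
  expect_error(read_spectrum(p4, kind = "emission"), "malformed row at line 2")
})

test_that("peak wavelength reports the maximum, ties to the blue", {
  expect_equal(peak_wavelength(spectrum(480, 1, kind = "emission")), 480)
  two_max <- spectrum(c(470, 480, 490), c(1, 0.5, 1), kind = "emission")
  expect_equal(peak_wavelength(two_max), 470)
  expect_error(peak_wavelength(spectrum(c(400, 500), c(0, 0),
                                        kind = "emission")),
               "degenerate")
  # generator ground truth: the synthetic donor's mode is the configured peak
  sp <- make_spectra(generator_config(donor = list(peak_nm = 491)))
  expect_equal(peak_wavelength(sp$donor_emission), 491, tolerance = 1e-8)
})

test_that("relative quantum yield follows the slope/refractive-index law", {
  # identical measurement and reference returns the reference yield
  expect_equal(quantum_yield(1, 1.36, 1, 1.36, 0.48), 0.48)
  # homogeneous of degree 1 in slope, -1 in reference slope
  expect_equal(quantum_yield(0.5, 1.36, 1, 1.36, 0.48), 0.24)
  expect_equal(quantum_yield(1, 1.36, 2, 1.36, 0.48), 0.24)
  # consistency anchor: a slope ratio of 0.47/0.48 at matched refractive
  # index reproduces the 85%-ethanol yield of L-Anap
  expect_equal(quantum_yield(0.47 / 0.48, 1.36, 1, 1.36, 0.48), 0.47)
  # refractive-index correction is quadratic
  expect_equal(quantum_yield(1, 1.4, 1, 1.33, 0.48),
               0.48 * (1.4 / 1.33)^2)
  expect_error(quantum_yield(1, 1.36, 0, 1.36), "nonzero")
  expect_warning(quantum_yield(3, 1.36, 1, 1.36, 0.48), "exceeds 1")
})

test_that("overlap integral matches the closed-form rectangular oracle", {
  donor <- rect_spectrum(500, 510, 1, "emission")
  acceptor <- rect_spectrum(500, 510, 1000, "absorption")
  # closed form: J = 1000 * (510^5 - 500^5) / 5 / (510 - 500)
  J_exact <- 1000 * (510^5 - 500^5) / 5 / 10
  expect_equal(overlap_integral(donor, acceptor), J_exact,
               tolerance = 1e-5)
})

test_that("overlap integral is donor-scale invariant and acceptor-linear", {
  sp <- make_spectra(generator_config(seed = 3))
  d <- sp$donor_emission; a <- sp$acceptor_absorption
  J <- overlap_integral(d, a)
  for (c_scale in c(0.01, 7, 1e4)) {
    d2 <- spectrum(d$wavelengths_nm, d$values * c_scale, kind = "emission")
    expect_equal(overlap_integral(d2, a), J, tolerance = 1e-12)
  }
  a3 <- spectrum(a$wavelengths_nm, a$values * 3, kind = "absorption")
  expect_equal(overlap_integral(d, a3), 3 * J, tolerance = 1e-12)
  # zero acceptor kills the overlap
  a0 <- spectrum(a$wavelengths_nm, a$values * 0, kind = "absorption")
  expect_equal(overlap_integral(d, a0), 0)
})

test_that("disjoint spectral supports yield zero overlap with a warning", {
  donor <- rect_spectrum(400, 450, 1, "emission")
  acceptor <- rect_spectrum(600, 650, 100, "absorption")
  expect_warning(J <- overlap_integral(donor, acceptor), "do not overlap")
  expect_equal(J, 0)
})

test_that("the integration window restricts the overlap numerator only", {
  sp <- make_spectra(generator_config(seed = 5))
  J_full <- overlap_integral(sp$donor_emission, sp$acceptor_absorption)
  J_win <- overlap_integral(sp$donor_emission, sp$acceptor_absorption,
                            window = c(450, 550))
  expect_lt(J_win, J_full)
  expect_gt(J_win, 0)
})
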