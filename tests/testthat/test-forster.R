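test_that("R0 follows the sixth-root scaling law in each factor", {
  base <- compute_R0(Q = 0.31, J = 5e12)
  expect_equal(compute_R0(0.62, 5e12), base * 2^(1 / 6))
  expect_equal(compute_R0(0.31, 1e13), base * 2^(1 / 6), tolerance = 1e-12)
  expect_equal(compute_R0(0.31, 5e12, kappa_squared = 4 / 3),
               base * 2^(1 / 6))
  expect_equal(compute_R0(0.31, 5e12, refractive_index = 1.33 * 2^(1 / 4)),
               base / 2^(1 / 6))
  expect_warning(r0 <- compute_R0(0.31, 0), "no spectral overlap")
  expect_equal(r0, 0)
  expect_error(compute_R0(1.2, 5e12), "Q must")
})

test_that("R0 from generated spectra matches the generator's analytic value", {
  cfg <- generator_config(seed = 2)
  sp <- make_spectra(cfg)
  J <- overlap_integral(sp$donor_emission, sp$acceptor_absorption)
  R0 <- compute_R0(cfg$donor$quantum_yield, J)
  expect_lt(abs(R0 - sp$R0_true), 0.1)
  # and the study-condition defaults put R0 in the reported range
  expect_gt(sp$R0_true, 16)
  expect_lt(sp$R0_true, 19)
})

test_that("Forster efficiency and distance invert each other", {
  R0 <- 17.7
  expect_equal(forster_efficiency(R0, R0), 0.5)
  expect_equal(forster_efficiency(2 * R0, R0), 1 / 65)
  expect_equal(forster_efficiency(12.27, 17.7), 0.90, tolerance = 1e-3)
  expect_equal(forster_distance(0.5, R0)$r_angstrom, R0)
  expect_equal(forster_distance(1 / 65, 10)$r_angstrom, 20)
  for (E in c(1e-6, 0.05, 0.3, 0.5, 0.7, 0.95, 1 - 1e-6)) {
    r <- forster_distance(E, R0)$r_angstrom
    expect_equal(forster_efficiency(r, R0), E, tolerance = 1e-12)
  }
  expect_error(forster_distance(0, R0), "strictly in")
  expect_error(forster_distance(1, R0), "strictly in")
})

test_that("FWHM/sigma conversion matches its definition", {
  expect_equal(sigma_from_fwhm(0), 0)
  expect_equal(sigma_from_fwhm(2 * sqrt(2 * log(2))), 1)
  expect_equal(fwhm_from_sigma(sigma_from_fwhm(8)), 8)
  expect_error(sigma_from_fwhm(-1), "non-negative")
})

test_that("FCG forward model degenerates to Forster and stays monotone", {
  R0 <- 17.7
  mu <- seq(5, 40, by = 0.5)
  expect_equal(fcg_efficiency(mu, 0, R0), forster_efficiency(mu, R0))
  # sup-norm convergence as sigma -> 0
  expect_lt(max(abs(fcg_efficiency(mu, 0.01, R0) -
                      forster_efficiency(mu, R0))), 1e-4)
  # strictly decreasing in mu at a working width
  e <- fcg_efficiency(mu, sigma_from_fwhm(8), R0)
  expect_true(all(diff(e) < 0))
})

test_that("FCG matches a Monte-Carlo average over the distance ensemble", {
  R0 <- 17.7
  withr::local_seed(421)
  for (mu in c(10, 18, 25)) {
    for (fwhm in c(5, 10)) {
      mc <- fcg_mc_oracle(mu, sigma_from_fwhm(fwhm), R0, n = 2e5)
      expect_lt(abs(fcg_efficiency(mu, sigma_from_fwhm(fwhm), R0) - mc$mean),
                4 * mc$se)
    }
  }
})

test_that("distance heterogeneity raises efficiency beyond R0, lowers it below", {
  R0 <- 17.7
  sigma <- sigma_from_fwhm(8)
  for (mu in c(20, 25, 30))
    expect_gt(fcg_efficiency(mu, sigma, R0), forster_efficiency(mu, R0))
  for (mu in c(10, 12, 14))
    expect_lt(fcg_efficiency(mu, sigma, R0), forster_efficiency(mu, R0))
})

test_that("wider distributions flatten the efficiency-distance curve", {
  R0 <- 17.7
  mu <- seq(6, 38, by = 1)
  e5 <- fcg_efficiency(mu, sigma_from_fwhm(5), R0)
  e10 <- fcg_efficiency(mu, sigma_from_fwhm(10), R0)
  d <- e10 - e5
  # single sign change near R0: negative at short range, positive at long
  expect_lt(d[1], 0)
  expect_gt(d[length(d)], 0)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
})

test_that("FCG inversion round-trips and reports its attainable range", {
  R0 <- 17.7
  sigma <- sigma_from_fwhm(8)
  for (E in seq(0.05, 0.95, by = 0.1)) {
    d <- fcg_distance(E, R0, fwhm = 8)
    expect_equal(fcg_efficiency(d$r_angstrom, sigma, R0), E,
                 tolerance = 1e-6)
    expect_identical(d$model, "fcg")
  }
  # fwhm = 0 degenerates to the Forster inversion
  d0 <- fcg_distance(0.3, R0, fwhm = 0)
  expect_identical(d0$model, "forster")
  expect_equal(d0$r_angstrom, forster_distance(0.3, R0)$r_angstrom)
  expect_error(fcg_distance(0.99999, R0, fwhm = 8), "attainable range")
})

test_that("FCG inversion corrects distances away from the Forster values", {
  # averaging over the ensemble inflates apparent efficiency at long range,
  # so inverting through FCG lengthens low-E distances and shortens high-E
  R0 <- 17.7
  for (E in c(0.1, 0.2, 0.35))
    expect_gt(fcg_distance(E, R0, 8)$r_angstrom,
              forster_distance(E, R0)$r_angstrom)
  for (E in c(0.7, 0.8, 0.9))
    expect_lt(fcg_distance(E, R0, 8)$r_angstrom,
              forster_distance(E, R0)$r_angstrom)
})

test_that("fret_pair derives a consistent R0", {
  fp <- fret_pair("Anap-295", "Cu-TETAC", Q = 0.31, J = 5.4e12)
  expect_equal(fp$R0_angstrom,
               compute_R0(0.31, 5.4e12), tolerance = 1e-9)
})
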