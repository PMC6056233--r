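test_that("quench_experiment validates times and events", {
  expect_error(quench_experiment(c(0, 10, 5), c(1, 1, 1),
                                 data.frame(time = 5, label = "add_acceptor")),
               "strictly increasing")
  expect_error(quench_experiment(c(0, 10), c(1, 1),
                                 data.frame(time = 50, label = "add_acceptor")),
               "outside")
  expect_error(quench_experiment(c(0, 10), c(1, 1),
                                 data.frame(time = 5, label = "bogus")),
               "unknown event label")
})

test_that("background subtraction recovers the protein signal", {
  cfg <- generator_config(seed = 9, experiment = list(noise_sd_relative = 0))
  tr <- make_quench_trace(cfg, "test", R0 = 17.7)
  bg <- make_quench_trace(cfg, "no_protein_background", R0 = 17.7)
  # zero background leaves the trace unchanged
  zero_bg <- quench_experiment(bg$times, rep(0, length(bg$times)),
                               bg$events, construct = "no_protein_background")
  expect_equal(subtract_background(tr, list(zero_bg))$fluorescence,
               tr$fluorescence)
  # a trace equal to the background mean becomes identically zero
  expect_equal(max(abs(subtract_background(bg, list(bg))$fluorescence)), 0)
  # signal + known background: subtraction recovers the signal exactly
  clean <- subtract_background(tr, list(bg))
  resid <- clean$fluorescence - (tr$fluorescence - bg$fluorescence)
  expect_lt(max(abs(resid)), 1e-9)
  expect_identical(clean$events, tr$events)
  expect_error(subtract_background(tr, list()), "at least one")
  expect_error(subtract_background(tr, list(tr)), "no_protein_background")
})

test_that("fractional fluorescence extracts the plateau ratio", {
  flat <- step_trace(pre = 100, post = 100)
  expect_equal(fractional_fluorescence(flat)$F, 1)
  stepd <- step_trace(pre = 100, post = 40)
  f <- fractional_fluorescence(stepd)
  expect_equal(f$F, 0.40)
  expect_equal(f$sem, 0)
  # invariant under rescaling of the whole trace
  scaled <- quench_experiment(stepd$times, stepd$fluorescence * 37.5,
                              stepd$events)
  expect_equal(fractional_fluorescence(scaled)$F, 0.40)
  expect_error(fractional_fluorescence(step_trace(pre = 0, post = 0)),
               "degenerate")
  no_event <- quench_experiment(c(0, 10), c(1, 1),
                                data.frame(time = numeric(0),
                                           label = character(0)))
  expect_error(fractional_fluorescence(no_event), "no add_acceptor")
})

test_that("noisy quench traces recover the true quenched fraction", {
  # simulation check of the ratio + delta-method SEM at 1% noise
  cfg <- generator_config(seed = 77,
                          experiment = list(background_quench_fraction = 0,
                                            r_true_A = 15))
  R0 <- 17.7
  F_true <- (1 - forster_efficiency(15, R0))
  n_rep <- 300
  within3 <- 0
  for (k in seq_len(n_rep)) {
    cfg$seed <- 77L + k
    tr <- make_quench_trace(cfg, "test", R0 = R0)
    bg <- make_quench_trace(cfg, "no_protein_background", R0 = R0)
    f <- fractional_fluorescence(subtract_background(tr, list(bg)))
    if (abs(f$F - F_true) <= 3 * max(f$sem, 1e-6)) within3 <- within3 + 1
  }
  # 3-SEM coverage should be high (the window SEM is a noisy estimate
  # from 3 points, so demand a conservative 90%)
  expect_gt(within3 / n_rep, 0.90)
})

test_that("reversal check compares recovery against the pre-quench level", {
  cfg <- generator_config(seed = 5,
                          experiment = list(noise_sd_relative = 0,
                                            recovery_fraction = 0.95,
                                            background_quench_fraction = 0))
  tr <- make_quench_trace(cfg, "test", R0 = 17.7)
  rc <- reversal_check(tr)
  expect_true(rc$reversed)
  expect_equal(rc$recovered_fraction, 0.95, tolerance = 0.02)
  cfg$experiment$recovery_fraction <- 0.5
  rc2 <- reversal_check(make_quench_trace(cfg, "test", R0 = 17.7))
  expect_false(rc2$reversed)
  no_rev <- step_trace()
  expect_error(reversal_check(no_rev), "no add_reversal")
})

test_that("corrected efficiency follows the two-pathway formula", {
  expect_equal(efficiency_corrected(0.5, 1)$E, 0.5)
  expect_equal(efficiency_corrected(0.7, 0.7)$E, 0)
  # frozen closed form: F_site = 0.4, F_no_site = 0.9 -> E = 25/43
  expect_equal(efficiency_corrected(0.4, 0.9)$E, 25 / 43)
  expect_error(efficiency_corrected(0.9, 0.3), "control quenched more")
  expect_error(efficiency_corrected(0, 1), "must be > 0")
})

test_that("simplified efficiency is the plain ratio", {
  expect_equal(efficiency_simplified(0.5, 1)$E, 0.5)
  expect_equal(efficiency_simplified(0.7, 0.7)$E, 0)
  expect_equal(efficiency_simplified(0.4, 0.9)$E, 5 / 9)
  # negative efficiencies are reported, not clipped
  expect_lt(efficiency_simplified(1.02, 1)$E, 0)
})

test_that("the two efficiency formulas agree when background quenching is low", {
  for (fs in c(0.2, 0.5, 0.8)) {
    expect_equal(efficiency_corrected(fs, 1)$E, efficiency_simplified(fs, 1)$E)
    # convergence as the control approaches unity
    gap <- vapply(c(0.9, 0.99, 0.999), function(fn)
      abs(efficiency_corrected(fs, fn)$E - efficiency_simplified(fs, fn)$E),
      numeric(1))
    expect_true(all(diff(gap) < 0))
  }
  # monotone decreasing in F_site for both
  fs_grid <- seq(0.1, 0.9, by = 0.1)
  ec <- vapply(fs_grid, function(f) efficiency_corrected(f, 0.95)$E,
               numeric(1))
  es <- vapply(fs_grid, function(f) efficiency_simplified(f, 0.95)$E,
               numeric(1))
  expect_true(all(diff(ec) < 0))
  expect_true(all(diff(es) < 0))
})

test_that("Monte-Carlo propagation is seeded, unbiased and delta-consistent", {
  fs <- list(F = 0.4, sem = 0.006)
  fn <- list(F = 0.95, sem = 0.01)
  a <- propagate_mc(fs, fn, "corrected", cycles = 2e5, seed = 42)
  b <- propagate_mc(fs, fn, "corrected", cycles = 2e5, seed = 42)
  expect_identical(a$E, b$E)
  expect_identical(a$sem, b$sem)
  # zero input SEMs give the deterministic value with zero spread
  z <- propagate_mc(list(F = 0.4, sem = 0), list(F = 0.95, sem = 0),
                    "corrected", cycles = 1e4)
  expect_equal(z$E, efficiency_corrected(0.4, 0.95)$E)
  expect_equal(z$sem, 0)
  # small relative SEMs: MC spread matches the first-order delta method
  for (method in c("corrected", "simplified")) {
    mc <- propagate_mc(fs, fn, method, cycles = 5e5, seed = 7)
    dm <- delta_method_sem(fs, fn, method)
    expect_lt(abs(mc$sem - dm) / dm, 0.1)
  }
  # gross instability aborts
  expect_error(propagate_mc(list(F = 0.01, sem = 0.2),
                            list(F = 0.01, sem = 0.2),
                            "corrected", cycles = 1e4, seed = 1),
               "unstable propagation")
})

test_that("quench traces round-trip through CSV with their events", {
  tr <- make_quench_trace(generator_config(seed = 31), "test", R0 = 17.7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_quench_trace(tr, path)
  back <- read_quench_trace(path,
                            events = sub("\\.csv$", "_events.csv", path),
                            construct = "test", condition = "apo")
  expect_equal(back$times, tr$times)
  expect_equal(back$fluorescence, tr$fluorescence, tolerance = 1e-12)
  expect_equal(back$events$label, tr$events$label)
})
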