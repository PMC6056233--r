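#' Configuration for the synthetic tmFRET data generator
#'
#' Bundles the ground-truth parameters from which every synthetic artifact
#' is produced. Defaults emulate the study conditions of an
#' L-Anap / Cu2+-TETAC tmFRET experiment on a maltose-binding-protein-like
#' scaffold: donor emission peaking at 494 nm with a red tail, quantum
#' yield 0.31; a weak, broad metal d-d absorption band (peak extinction
#' 140 M^-1 cm^-1 at 590 nm, width 60 nm) whose overlap with the donor
#' yields R0 near 17.7 A; 10-s sampling; low (2%) background quenching;
#' near-complete (95%) reversal; 1% multiplicative noise; and a 280 uM
#' ligand dissociation constant sampled over 8 log-spaced concentrations.
#'
#' @param seed Integer seed; all generators are deterministic given it.
#' @param donor List: `peak_nm` (mode of the emission curve), `width_nm`
#'   (Gaussian scale), `skew` (>= 0; the red-side width is inflated by
#'   `1 + skew` and the blue side shrunk by `1/(1 + skew)`, keeping the
#'   mode at `peak_nm`), `quantum_yield`.
#' @param acceptor List: `peak_nm`, `width_nm`,
#'   `peak_extinction_M1cm1` (molar extinction at the peak).
#' @param experiment List: either `r_true_A` (rigid distance) or
#'   `mu_true_A` + `fwhm_true_A` (Gaussian distance distribution);
#'   `background_quench_fraction`, `noise_sd_relative` (in [0, 0.2]),
#'   `samples_per_plateau`, `recovery_fraction`, `sample_interval_s`,
#'   `tau_s` (exponential approach time constant).
#' @param titration List: `Kd_M`, `concentrations` (molar), `noise_sd`
#'   (relative SD of the multiplicative noise on fractional fluorescence).
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(
    seed = 1L,
    donor = list(),
    acceptor = list(),
    experiment = list(),
    titration = list()) {
  donor <- utils::modifyList(
    list(peak_nm = 494, width_nm = 35, skew = 0.4, quantum_yield = 0.31),
    donor)
  acceptor <- utils::modifyList(
    list(peak_nm = 590, width_nm = 60, peak_extinction_M1cm1 = 140),
    acceptor)
  experiment <- utils::modifyList(
    list(r_true_A = 17, mu_true_A = NULL, fwhm_true_A = NULL,
         background_quench_fraction = 0.02, noise_sd_relative = 0.01,
         samples_per_plateau = 10, recovery_fraction = 0.95,
         sample_interval_s = 10, tau_s = 5),
    experiment)
  titration <- utils::modifyList(
    list(Kd_M = 280e-6,
         concentrations = 10^seq(log10(1e-5), log10(1e-2), length.out = 8),
         noise_sd = 0.02),
    titration)
  stopifnot(donor$width_nm > 0, donor$skew >= 0,
            donor$quantum_yield > 0, donor$quantum_yield <= 1,
            acceptor$width_nm > 0, acceptor$peak_extinction_M1cm1 >= 0,
            experiment$noise_sd_relative >= 0,
            experiment$noise_sd_relative <= 0.2,
            experiment$background_quench_fraction >= 0,
            experiment$background_quench_fraction < 1,
            experiment$samples_per_plateau >= 2,
            experiment$sample_interval_s > 0, experiment$tau_s > 0,
            titration$Kd_M > 0, titration$noise_sd >= 0)
  structure(list(seed = as.integer(seed), donor = donor, acceptor = acceptor,
                 experiment = experiment, titration = titration),
            class = "generator_config")
}

# parametric spectral shapes shared by the 1-nm emitted spectra and the
# high-resolution analytic oracle
donor_shape <- function(wl, donor) {
  sdl <- donor$width_nm / (1 + donor$skew)
  sdr <- donor$width_nm * (1 + donor$skew)
  ifelse(wl < donor$peak_nm,
         exp(-0.5 * ((wl - donor$peak_nm) / sdl)^2),
         exp(-0.5 * ((wl - donor$peak_nm) / sdr)^2))
}
acceptor_shape <- function(wl, acceptor) {
  acceptor$peak_extinction_M1cm1 *
    exp(-0.5 * ((wl - acceptor$peak_nm) / acceptor$width_nm)^2)
}

#' Generate a donor emission / acceptor absorption spectrum pair
#'
#' Emits both spectra on a 1-nm grid spanning 300-650 nm, together with the
#' ground-truth overlap integral and Forster radius computed analytically
#' from the same parametric shapes by high-resolution (0.02-nm) quadrature.
#' `J_true`/`R0_true` are therefore an independent oracle for
#' [overlap_integral()] and [compute_R0()] applied to the emitted grids.
#'
#' @param cfg A [generator_config()].
#' @param kappa_squared,refractive_index Constants for the R0 oracle.
#' @return List with `donor_emission`, `acceptor_absorption` (both
#'   [spectrum()]s), `J_true` (M^-1 cm^-1 nm^4) and `R0_true` (Angstrom).
#' @export
make_spectra <- function(cfg = generator_config(), kappa_squared = 2 / 3,
                         refractive_index = 1.33) {
  stopifnot(inherits(cfg, "generator_config"))
  wl <- seq(300, 650, by = 1)
  dem <- spectrum(wl, donor_shape(wl, cfg$donor), kind = "emission",
                  label = "synthetic L-Anap-like emission")
  aab <- spectrum(wl, acceptor_shape(wl, cfg$acceptor), kind = "absorption",
                  label = "synthetic Cu2+-TETAC-like absorption")
  hi <- seq(300, 650, by = 0.02)
  fd <- donor_shape(hi, cfg$donor)
  ea <- acceptor_shape(hi, cfg$acceptor)
  J_true <- trapz(hi, fd * ea * hi^4) / trapz(hi, fd)
  R0_true <- if (J_true > 0)
    0.2108 * (kappa_squared * refractive_index^-4 *
                cfg$donor$quantum_yield * J_true)^(1 / 6)
  else 0
  list(donor_emission = dem, acceptor_absorption = aab,
       J_true = J_true, R0_true = R0_true)
}

# ground-truth apparent efficiency for the configured experiment
true_efficiency <- function(cfg, R0) {
  ex <- cfg$experiment
  if (!is.null(ex$mu_true_A)) {
    fcg_efficiency(ex$mu_true_A, sigma_from_fwhm(ex$fwhm_true_A %||% 0), R0)
  } else {
    forster_efficiency(ex$r_true_A, R0)
  }
}
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a stepwise quench/recovery time course
#'
#' Emulates a fluorometer record: a unity plateau, addition of the acceptor
#' (exponential approach, time constant `tau_s`, fast relative to the 10-s
#' sampling) to the quenched level, then a reversal reagent restoring
#' `recovery_fraction` of the initial fluorescence. The quenched level is
#' \eqn{F = (1 - E)(1 - b)} for the test construct (E from the configured
#' true distance and `R0`, b the background quench fraction) and
#' \eqn{1 - b} for the no-site control (no specific FRET). A small,
#' slowly drifting non-protein baseline rides on every record; the
#' no-protein background construct carries only that baseline, so
#' averaged backgrounds subtracted via [subtract_background()] recover
#' the protein signal. Noise is multiplicative
#' Gaussian with relative SD `noise_sd_relative`, reflecting shot/lamp
#' noise that scales with signal.
#'
#' @param cfg A [generator_config()].
#' @param construct `"test"`, `"no_site_control"` or
#'   `"no_protein_background"`.
#' @param condition `"apo"` or `"ligand"` (label only; the configured
#'   distance defines the signal).
#' @param R0 Forster radius used to convert the configured true distance
#'   into the quenched level; defaults to the config's own spectral oracle.
#' @param scale Overall fluorescence scale (default 1).
#' @return A [quench_experiment()] with `add_acceptor` and `add_reversal`
#'   events; attribute `"F_true"` carries the noise-free quenched fraction.
#' @export
make_quench_trace <- function(cfg = generator_config(),
                              construct = c("test", "no_site_control",
                                            "no_protein_background"),
                              condition = c("apo", "ligand"),
                              R0 = NULL, scale = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  construct <- match.arg(construct)
  condition <- match.arg(condition)
  ex <- cfg$experiment
  if (is.null(R0)) R0 <- make_spectra(cfg)$R0_true
  E_true <- true_efficiency(cfg, R0)
  b <- ex$background_quench_fraction
  F_true <- switch(construct,
                   test = (1 - E_true) * (1 - b),
                   no_site_control = 1 - b,
                   no_protein_background = 1)
  dt <- ex$sample_interval_s
  n_pl <- ex$samples_per_plateau
  times <- seq(0, by = dt, length.out = 3L * n_pl)
  t_acc <- times[n_pl] + dt / 2
  t_rev <- times[2L * n_pl] + dt / 2
  level <- numeric(length(times))
  approach <- function(t, t0, from, to)
    to + (from - to) * exp(-(t - t0) / ex$tau_s)
  rec <- ex$recovery_fraction
  for (i in seq_along(times)) {
    t <- times[i]
    level[i] <- if (t < t_acc) 1
    else if (t < t_rev) approach(t, t_acc, 1, F_true)
    else approach(t, t_rev, F_true, rec)
  }
  # non-protein baseline (buffer Raman etc.) with a slow linear drift; it
  # rides on every record and is what background subtraction removes
  baseline <- 0.05 * (1 - 0.1 * (times - times[1L]) / diff(range(times)))
  level <- if (construct == "no_protein_background") baseline
           else level + baseline
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed + match(construct, c("test", "no_site_control",
                                         "no_protein_background")) * 1000L +
             match(condition, c("apo", "ligand")))
  noisy <- level * scale *
    (1 + stats::rnorm(length(level), 0, ex$noise_sd_relative))
  out <- quench_experiment(
    times, noisy,
    events = data.frame(time = c(t_acc, t_rev),
                        label = c("add_acceptor", "add_reversal")),
    construct = construct, condition = condition)
  attr(out, "F_true") <- F_true
  attr(out, "E_true") <- E_true
  out
}

#' Generate a saturable titration curve
#'
#' Fractional fluorescence following the single-site isotherm
#' F(L) = F_start + (F_end - F_start) L / (L + Kd), with multiplicative
#' Gaussian noise of relative SD `noise_sd` at each concentration — the
#' same signal-scaled noise model as the quench traces, since both come
#' from the same instrument.
#'
#' @param cfg A [generator_config()]; uses the `titration` block and
#'   `seed`.
#' @param F_start,F_end Asymptotes. The defaults (0.7 at zero ligand,
#'   0.3 at saturation) emulate a ligand-driven clamshell closure observed
#'   through the acceptor-conjugated construct: apo quenching at a ~21 A
#'   separation to strong quenching at ~13 A.
#' @return A [titration_curve()]; attribute `"Kd_true"` carries the
#'   ground-truth dissociation constant.
#' @export
make_titration <- function(cfg = generator_config(), F_start = 0.7,
                           F_end = 0.3) {
  stopifnot(inherits(cfg, "generator_config"))
  ti <- cfg$titration
  L <- ti$concentrations
  if (length(L) < 3L) stop("at least 3 concentrations", call. = FALSE)
  f <- F_start + (F_end - F_start) * L / (L + ti$Kd_M)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed + 7919L)
  fn <- f * (1 + stats::rnorm(length(f), 0, ti$noise_sd))
  out <- titration_curve(L, fn, sems = ti$noise_sd * f,
                         ligand_label = "synthetic titration")
  attr(out, "Kd_true") <- ti$Kd_M
  out
}

#' Write a minimal synthetic PDB fixture
#'
#' Produces a syntactically valid single-model PDB file with one CB atom
#' (alanine) per supplied coordinate, for exercising the crystal-benchmark
#' path without real deposited structures. Coordinates are written at the
#' PDB's native 3-decimal precision.
#'
#' @param coords Data frame with columns `resno`, `x`, `y`, `z` and
#'   optionally `chain` (default `"A"`).
#' @param path Output path (default: a tempfile ending in `.pdb`).
#' @return `path`, invisibly.
#' @export
make_pdb_fixture <- function(coords, path = tempfile(fileext = ".pdb")) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("resno", "x", "y", "z") %in% names(coords)))
  if (is.null(coords$chain)) coords$chain <- "A"
  lines <- c(
    "HEADER    SYNTHETIC FIXTURE",
    "REMARK    synthetic coordinates generated by tmfret::make_pdb_fixture",
    vapply(seq_len(nrow(coords)), function(i) {
      sprintf("ATOM  %5d  CB  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              i, substr(coords$chain[i], 1, 1), as.integer(coords$resno[i]),
              coords$x[i], coords$y[i], coords$z[i])
    }, character(1)),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic demo dataset
#'
#' Emits, under `dir`: the donor/acceptor spectra, quench traces with event
#' sidecars for the test construct, the no-site control, and several
#' no-protein backgrounds, a titration table, and a synthetic PDB fixture,
#' plus a `ground_truth.json` recording the generating parameters. These
#' are exactly the files the readers and [run_pipeline()] consume.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if missing).
#' @param n_background Number of no-protein background replicates
#'   (default 6).
#' @return `dir`, invisibly.
#' @export
write_demo_dataset <- function(cfg = generator_config(), dir,
                               n_background = 6L) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- make_spectra(cfg)
  write_spectrum(sp$donor_emission, file.path(dir, "donor_emission.csv"))
  write_spectrum(sp$acceptor_absorption,
                 file.path(dir, "acceptor_absorption.csv"))
  for (con in c("test", "no_site_control")) {
    tr <- make_quench_trace(cfg, construct = con)
    write_quench_trace(tr, file.path(dir, paste0("trace_", con, ".csv")))
  }
  for (k in seq_len(n_background)) {
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + 100L + k
    tr <- make_quench_trace(cfg_k, construct = "no_protein_background")
    write_quench_trace(tr, file.path(dir, sprintf("background_%02d.csv", k)))
  }
  ti <- make_titration(cfg)
  utils::write.csv(data.frame(concentration_M = ti$concentrations,
                              F = ti$F_values, sem = ti$sems),
                   file.path(dir, "titration.csv"), row.names = FALSE,
                   quote = FALSE)
  make_pdb_fixture(
    data.frame(resno = c(237, 295),
               x = c(0, cfg$experiment$r_true_A %||% 17), y = 0, z = 0),
    file.path(dir, "synthetic_structure.pdb"))
  truth <- list(seed = cfg$seed, R0_true = sp$R0_true, J_true = sp$J_true,
                donor = cfg$donor, acceptor = cfg$acceptor,
                experiment = cfg$experiment,
                titration = list(Kd_M = cfg$titration$Kd_M))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
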