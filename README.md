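# tmfret

Transition-metal FRET (tmFRET) measures short intramolecular distances —
roughly 10–20 Å, below the working range of conventional FRET pairs — by
quenching a small fluorophore (such as the noncanonical amino acid L-Anap)
with a nearby bound transition-metal ion (Cu²⁺ chelated at an engineered
di-histidine site, or Cu²⁺-TETAC conjugated to an introduced cysteine).
`tmfret` implements the complete quantitative chain that turns raw
fluorometer records into distances, for structural biologists and
biophysicists running such experiments:

1. **Photophysics.** Relative quantum yields from fluorescence-vs-absorbance
   slopes, `Q_M = Q_ref (slope_M/slope_ref)(η_M²/η_ref²)`; the spectral
   overlap integral `J = ∫F_D(λ) ε_A(λ) λ⁴ dλ / ∫F_D(λ) dλ`
   (M⁻¹cm⁻¹nm⁴); and the Förster radius
   `R₀ = 0.2108 (κ² η⁻⁴ Q J)^{1/6}` Å, with κ² = 2/3 and η = 1.33 by
   default.
2. **Quenching analysis.** Fractional fluorescence `F = F_metal / F_no-metal`
   from event-annotated time courses (plateau windows around the acceptor
   addition), averaged no-protein background subtraction, reversal checks,
   and FRET efficiency corrected for nonspecific transfer with a
   no-acceptor-site control: `E = 1 − 1/(1 + 1/F_site − 1/F_no_site)`
   (or the simplified ratio `E = 1 − F_site/F_no_site`), with uncertainty
   by normal-theory Monte-Carlo resampling of the measured F ± SEM.
3. **Distances.** The Förster inversion `r = R₀ (1/E − 1)^{1/6}` and the
   FCG model — the Förster curve numerically convolved with a Gaussian
   distribution of distances (parameterized by FWHM, 8 Å ⇒ σ = 3.4 Å) —
   which corrects the systematic bias that distance heterogeneity imposes
   on point-distance estimates.
4. **Supporting analyses.** Single-site binding isotherm fits
   (`F(L) = F_start + (F_end − F_start) L/(L + K_d)`), Cβ–Cβ benchmark
   distances from PDB coordinates, and RMSD comparison of measured vs.
   crystallographic distances.
5. **Synthetic data.** A seeded generator that emulates every input the
   pipeline consumes — environment-shifted emission spectra, weak metal
   d-d absorption bands, stepwise quench/recovery traces with
   signal-scaled noise, saturable titrations, and minimal PDB fixtures —
   so the full chain is testable end to end.

## Worked example

```r
library(tmfret)

# synthetic study: L-Anap-like donor (Q = 0.31), Cu2+-TETAC-like acceptor
cfg <- generator_config(seed = 1)
sp  <- make_spectra(cfg)
J   <- overlap_integral(sp$donor_emission, sp$acceptor_absorption)
R0  <- compute_R0(Q = 0.31, J = J)
c(J = J, R0 = R0)
#>            J           R0
#> 5.402076e+12 1.775312e+01

# a quench experiment at a true donor-acceptor distance of 17 A, 1% noise
tr  <- make_quench_trace(cfg, "test", R0 = R0)
ctl <- make_quench_trace(cfg, "no_site_control", R0 = R0)
bg  <- make_quench_trace(cfg, "no_protein_background", R0 = R0)
f_site <- fractional_fluorescence(subtract_background(tr, list(bg)))
f_ctl  <- fractional_fluorescence(subtract_background(ctl, list(bg)))
eff <- propagate_mc(f_site, f_ctl, method = "corrected",
                    cycles = 1e6, seed = 1)
eff
#> <E = 0.5700 +/- 0.0059 (corrected, 1000000 MC cycles)>

forster_distance(eff$E, R0)   # rigid-distance inversion
#> <distance: 16.94 A (forster, E = 0.570)>
fcg_distance(eff$E, R0, fwhm = 8)  # Gaussian-ensemble inversion
#> <distance: 16.92 A (fcg, FWHM = 8 A, E = 0.570)>
```

The efficiency (0.570 ± 0.006) sits on the Förster curve for a 17-Å
separation with this pair's R₀ of 17.75 Å, and both inversions recover the
generating distance to within the noise; at efficiencies far from 0.5 the
two models deviate in a characteristic direction (FCG longer at low E,
shorter at high E).

A configuration-driven run over files (spectra, traces, events, titrations,
structures) is available through `run_pipeline("config.yaml")`, and a thin
command-line front end with `simulate` / `r0` / `efficiency` / `distance` /
`titration` / `benchmark` / `run` subcommands is installed at
`inst/scripts/tmfret`.

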