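---
title: "Models and methods behind tmfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tmfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmfret)
```

`tmfret` analyzes transition-metal FRET experiments, in which a small
fluorophore — typically the noncanonical amino acid L-Anap, incorporated
at a chosen site by amber-codon suppression — is quenched by a transition
metal ion bound a short distance away, either at an engineered
di-histidine (HH) site or chelated by a cysteine-reactive cyclen
(Cu²⁺-TETAC). Because metal-ion acceptors have weak, broad absorption,
the Förster radius is short (12–18 Å) and the method resolves distances
conventional FRET cannot. This vignette describes the models, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## From spectra to the Förster radius

The donor quantum yield is measured relative to a reference solvent by
comparing slopes of fluorescence intensity against absorbance:

$$Q_M = Q_{ref}\,\frac{slope_M}{slope_{ref}}\,\frac{\eta_M^2}{\eta_{ref}^2}.$$

For L-Anap the customary reference is ethanol, $Q = 0.48$. The ethanol
mixture whose emission spectrum best matches the protein-incorporated
fluorophore serves as the environment mimic; a 20%-ethanol-like
environment gives $Q \approx 0.31$ and an 85%-ethanol-like one
$Q \approx 0.47$. `quantum_yield()` implements the relation and warns
(rather than errs) on values above 1, which indicate an inconsistent
reference rather than an arithmetic failure.

The spectral overlap integral uses the standard λ⁴-weighted form,

$$J = \frac{\int F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,
  d\lambda}{\int F_D(\lambda)\,d\lambda}
  \quad [\mathrm{M^{-1}cm^{-1}nm^4}],$$

with both spectra linearly interpolated onto the union of their
wavelength grids and integrated by the trapezoid rule. Spectra from
modern fluorometers are densely sampled (≤ 1 nm), so higher-order
quadrature would change J well below the uncertainty of the extinction
calibration; against a 0.02-nm analytic quadrature of the generator's
parametric shapes, the 1-nm trapezoid agrees to better than 0.1%. The
donor normalization always runs over the full donor support, making J
exactly invariant under donor rescaling; an optional window restricts
only the numerator, for instruments whose red calibration is poor.
Negative emission samples (baseline noise) are clipped to zero with a
reported count; negative extinction is rejected outright.

The Förster radius follows the photophysics convention for J in
M⁻¹cm⁻¹nm⁴:

$$R_0 = 0.2108\,\left(\kappa^2\,\eta^{-4}\,Q\,J\right)^{1/6}
  \ \text{Å},$$

with defaults $\kappa^2 = 2/3$ (isotropic averaging — a good assumption
for metal-ion acceptors, whose d-d transitions are nearly degenerate in
orientation) and $\eta = 1.33$ (aqueous). Both are overridable
everywhere they enter. The sixth root makes R₀ robust: a 20% error in Q
moves R₀ by only ~3%.

## Quench traces to efficiency

Fractional fluorescence is a plateau ratio,
$F = F_{\text{with metal}} / F_{\text{without metal}}$. The default
plateau window is the last 3 samples before the relevant transition
(acceptor addition, next event, or trace end). Three samples at the
typical 10-s sampling interval uses only steady-state data while staying
robust to the slow drifts real records show; the window width is a
parameter (`window_points`). The SEM of F is propagated from the two
window standard errors by the first-order delta method for a ratio.
Before any ratio is taken, an averaged no-protein background trace —
interpolated to the record's time base — is subtracted, removing buffer
and reagent signal that is not protein fluorescence.

Two efficiency estimators are provided. The corrected form treats
specific FRET and background transfer (e.g. solution quenching by free
acceptor) as independent de-excitation pathways referenced against a
control construct lacking the acceptor site:

$$E = 1 - \frac{1}{1 + 1/F_{site} - 1/F_{nosite}},$$

and the simplified form is the plain ratio $E = 1 - F_{site}/F_{nosite}$,
which accounts for nonspecific fluorescence loss but not background
transfer. They coincide exactly at $F_{nosite} = 1$ and differ by less
than 0.01 whenever control quenching is under ~2%, so with clean controls
the choice is immaterial. Negative efficiencies are reported, not
clipped: clipping would bias no-site controls, whose true efficiency is
zero, upward.

Uncertainty is propagated by Monte-Carlo resampling in the style of
measurement-uncertainty engines: each cycle draws both F values from
independent normals (measured mean, measured SEM), evaluates the chosen
formula, and discards draws where it is undefined (non-positive F, or a
control apparently quenching more than the test construct). The default
is 10⁶ cycles; rejections are counted and more than 50% aborts the
propagation. Sampling is not truncated at zero because the inputs are
normal-theory summaries; at the small relative SEMs of practical data the
rejection rate is nil and the MC spread matches the delta method within a
few tenths of a percent — a cross-check the test suite enforces at 10%.

## Distance models

The Förster inversion $r = R_0(1/E - 1)^{1/6}$ assumes a single rigid
distance. Proteins are ensembles, so the package also implements the
Förster-convolved-Gaussian (FCG) model: the apparent efficiency at mean
distance μ is the Förster curve averaged over a Gaussian of width σ
(parameterized by FWHM $= 2\sqrt{2\ln 2}\,\sigma$; FWHM 8 Å ⇒
σ ≈ 3.4 Å, a typical backbone-ensemble width):

$$E_{app}(\mu) = \int_0^\infty N(r;\mu,\sigma)\,
  \frac{1}{1+(r/R_0)^6}\,dr.$$

Numerics: the Gaussian is truncated at $r > 0$ and renormalized over the
truncated support — negative distances are unphysical, and at the working
regime μ ≫ σ the correction is negligible but well-defined; quadrature is
trapezoidal over μ ± 6σ at a step no coarser than σ/50 (the suite checks
agreement with a 10⁶-draw Monte-Carlo average within its standard error);
σ = 0 short-circuits exactly to the Förster expression. Because the
Förster curve is convex beyond its inflection and concave near
saturation, averaging flattens the efficiency–distance relation: ensemble
means beyond R₀ show *more* apparent transfer than a rigid distance
would, and means below R₀ show *less*, with a single crossing near R₀.
Inverting measured efficiencies through the FCG curve therefore lengthens
low-efficiency distances and shortens high-efficiency ones relative to
the plain Förster inversion — the heterogeneity correction.

Inversion uses bracketing root-finding on μ ∈ [0.2 R₀, 3 R₀] (the
forward curve is strictly decreasing, so the root is unique), refined to
|ΔE| < 10⁻⁶; efficiencies outside the attainable range of the forward
model for the given (R₀, FWHM) raise an error that reports the attainable
bounds, since such values support only a distance bound, not an estimate.

## Binding isotherms

Titrations are fit to the single-site rectangular hyperbola
$F(L) = F_{start} + (F_{end}-F_{start})\,L/(L+K_d)$ by
Levenberg-Marquardt (via `minpack.lm`), with the Hill coefficient fixed
at 1 — the model the data are meant to report — and a free-Hill variant
available but off by default. Both asymptotes float by default, and the
fit report flags a $K_d$ outside the spanned concentration range as
extrapolated. Initialization is from the data extremes and the
concentration nearest half-amplitude. Weighted (1/SEM²) least squares is
optional because published plots often show mean ± SEM without stating
the weighting used; both variants are reproducible here.

## Crystal benchmarking

Measured distances are compared against Cβ–Cβ separations computed from
PDB coordinates (`bio3d` parsing; CA fallback for glycine), the standard
proxy for probe-attachment-site distances. The comparison report pairs by
label and gives the RMSD. No probe-position model is applied: fluorophore
and metal sit off the backbone, and residual discrepancy between
FRET-derived and Cβ distances partly reflects that geometry. Residue
numbering follows the coordinate file's author numbering; offsets between
construct and deposited numbering must be resolved by the caller.

## The synthetic generator

All tests run on synthetic data, generated from parametric ground truth:

* **Spectra** — the donor is a bifurcated Gaussian (mode exactly at the
  configured peak; red-side width inflated by 1 + skew) emulating
  L-Anap's asymmetric, environment-sensitive emission with its 494-nm
  aqueous peak; the acceptor is a Gaussian band. Default acceptor scale
  (peak ε = 140 M⁻¹cm⁻¹ at 590 nm, width 60 nm) is a realistic weak
  metal d-d band chosen so that, with Q = 0.31, the pair's R₀ is ≈ 17.7 Å
  — the regime the method targets. The generator computes its own J and
  R₀ analytically at 0.02-nm resolution, providing an independent oracle
  for the 1-nm pipeline path.
* **Quench traces** — plateaus joined by exponential approaches (default
  time constant 5 s against 10-s sampling, i.e. quenching completes
  within one or two samples, as cysteine-conjugation kinetics do) rather
  than instantaneous steps, so plateau-window logic is genuinely
  exercised; a small drifting non-protein baseline rides on every record
  and is what background subtraction removes; noise is multiplicative
  (relative SD, default 1%) because fluorometer shot and lamp noise
  scale with signal. Test constructs quench to $(1-E)(1-b)$, no-site
  controls to $1-b$ (background quenching b, default 2%), and reversal
  restores a configurable fraction (default 95%).
* **Titrations** — single-site isotherm between fractional-fluorescence
  asymptotes 0.7 (apo) and 0.3 (ligand-saturated), emulating a
  ligand-driven domain closure seen through the acceptor-conjugated
  construct, with 2% relative noise and 8 log-spaced concentrations
  around a 280 µM dissociation constant. Under these conditions repeated
  fits recover $K_d$ with a median relative error of ~8%; an additive
  0.02 noise floor instead would put the information-theoretic best case
  near 14%, which is why the signal-scaled model (matching the
  instrument) is the default.
* **Structures** — minimal single-model PDB files with CB atoms at
  requested coordinates, written at the format's 3-decimal precision.
  These are synthetic stand-ins: they exercise the parsing and geometry
  path, not crystallographic reality.

What the generator does **not** emulate: instrument spectral response and
inner-filter effects, photobleaching beyond the subtracted background,
binding kinetics (only equilibrium plateaus), non-Gaussian distance
distributions, orientation-factor distributions beyond scalar κ², and
pixel-level image statistics (imaging data enter as per-ROI mean
intensity time courses). Passing tests therefore demonstrate correctness
of the analysis chain under the stated statistical model, not robustness
to every instrument pathology.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. The test suite's simulation checks use a few hundred
replicates per condition (e.g. 250 quench-recovery replicates per true
distance, 500 isotherm fits, 10⁶-cycle Monte-Carlo propagation), sizes at
which the sampling error of the checked summaries is several times
smaller than the tolerances asserted. The acceptance script uses 200
replicates per distance condition and 300 isotherm fits, and reports the
sample size alongside every number it writes.

## Known limitations

* The corrected-efficiency formula models background transfer as an
  independent quenching pathway; if background instead scales the signal
  multiplicatively, the simplified ratio is exact and the corrected form
  carries a small (< 1% of E at 2% background) bias. Both are provided.
* FCG assumes a single Gaussian population with a width chosen a priori;
  the data do not constrain FWHM, and reported distances shift by a few
  tenths of an Ångström between FWHM 5 and 10 Å at moderate
  efficiencies.
* κ² = 2/3 is an assumption, not a measurement; for donor-metal pairs it
  is usually benign, but rigid, oriented fluorophores would violate it.
* Quantum-yield transfer from solvent mimics assumes the mixture
  reproduces the protein environment and that no endogenous quenchers
  act at the incorporation site.
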