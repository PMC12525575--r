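---
title: "Models and methods: low-field tissue relaxometry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: low-field tissue relaxometry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxometry)
```

This vignette is the package's own account of the models it fits, the
numerical choices behind the fitters, what the synthetic-data generator does
and does not emulate, and the design decisions that were genuinely open.

## The physical picture

Tissue is a crowded, heterogeneous mixture of water and macromolecules.
At low magnetic fields, the ¹H spin–lattice relaxation rate R₁ depends on
the resonance frequency ν, and that dependence reports on slow molecular
motion. Fast-field-cycling experiments sample R₁ from 10 kHz to 10 MHz;
a time-domain instrument adds R₁ and the spin–spin decay at 18.7 MHz.

Three empirical regularities drive the whole analysis:

1. **Power-law dispersion.** R₁(ν) = C·ν^(−α) describes the full measured
   range, with α ≈ 0.27–0.33 for lung tissue regardless of pathological
   state. Exponents this low are characteristic of highly restricted
   dynamics; polymer reptation theory predicts α = 0.25 for the
   intermolecular relaxation contribution, which is the closest theoretical
   anchor.
2. **Single-exponential spin–lattice recovery.** Saturation-recovery curves
   are mono-exponential at every frequency, so each profile point is one
   rate.
3. **Bi-exponential spin–spin decay.** CPMG magnetization at 18.7 MHz needs
   two components, M(t) = A_slow·e^(−R₂,slow·t) + A_fast·e^(−R₂,fast·t),
   interpreted as two proton pools (bound water vs macromolecular protons).
   The fast component always has the smaller amplitude, and
   R₂,slow/R₁ ≥ 1 holds on quantum-mechanical grounds — the package treats
   a violation as a data-quality flag, not an error.

## Parameterization choices

**Anchored power-law pre-factor.** The conventional pre-factor C has units
s^(α−1), which couples its scale to the exponent and makes the least-squares
problem badly conditioned. The package stores the model rate at a reference
frequency instead, `r1_at_ref` at ν_ref = 1 MHz, so both parameters are
O(1–100) and unit-clean; C = r1_at_ref·ν_ref^α when needed. Frequencies are
plain ν in Hz everywhere. A power law has the same exponent in ν and in
angular frequency ω = 2πν — only the pre-factor rescales — so nothing is
lost by avoiding ω.

**Canonical component order.** `bi_exp_fit()` relabels components so
r2_slow ≤ r2_fast; swapping labels before construction yields an identical
curve and an identical object. All downstream ratios rely on this.

**Saturation-recovery sign convention.** M(t) = M0·(1 − e^(−R₁t)), matching
the saturation-recovery sequence actually used; an inversion-recovery form
is deliberately not provided.

## Fitting numerics

All nonlinear fits use Levenberg–Marquardt (`minpack.lm::nlsLM`) with tight
tolerances (ftol = ptol = 1e−14, ≤ 500 iterations) and deterministic,
data-driven starting values — no random restarts, so identical input gives
identical output.

- **Dispersion:** started from ordinary least squares of log R₁ on log ν
  (already exact on noise-free data), then refined on the *linear* scale.
  Residuals are unweighted by default; 1/σ² weighting is applied only on
  request when the profile carries uncertainties, since the weighting used
  for the published fits is not documented.
- **Bi-exponential decay:** started by exponential peeling — the last third
  of the echoes is fitted log-linearly for the slow component, which is
  subtracted, and the early-time remainder fitted for the fast component.
  Positivity bounds keep amplitudes ≥ 0 and rates > 0. If the peeled start
  makes the Jacobian singular (it collapses on mono-exponential input) a
  single separated restart is tried before reporting a fit error.
- **Degenerate-component flag:** a fitted rate ratio below 1.05, or a fast
  amplitude below 10⁻⁶ of the slow one, marks the decomposition as
  effectively mono-exponential. The 1.05 threshold sits far below the
  1.9–4.9 ratios seen in real lung tissue, so the flag cannot fire on
  genuinely bi-exponential data; the amplitude clause is needed because on
  mono-exponential input the optimizer drives A_fast to zero while the fast
  rate stays unidentified at an arbitrary value.
- **Model selection:** both shapes are fitted and the bi-exponential model
  is chosen only when the small-sample-corrected AIC improves by more than
  10. The exponentiality classes are asserted, not argued, in the source
  data; a fixed conservative threshold makes the classification
  reproducible. At the generator's default noise (0.5 % of the initial
  amplitude, 1000 echoes) a rate ratio of 3 clears the threshold by orders
  of magnitude while a ratio of 1.1 stays below it.
- **R²** is always 1 − SSR/SST with SST about the mean signal, on the
  linear scale — the same convention as the published fit-quality figures
  (0.993–0.997 for dispersions, 0.998–0.999 for decays).
- **No baseline terms.** The fitted expressions contain no additive offset,
  matching the models above; the generator produces zero-baseline signals.
  Detector offsets must be removed upstream.

**Quadrupole-peak masking.** Between roughly 2 and 4 MHz, ¹H–¹⁴N
cross-relaxation produces small frequency-specific enhancements
("quadrupole peaks") on top of the power law. They are too weak for
quantitative analysis, so the package handles them purely as a nuisance:
`fit_dispersion_power_law(..., exclude_band = c(2e6, 4e6))` omits the band.
No band is excluded by default because the effect is not always present.

## The ξ marker: data mode vs model mode

ξ is the percent drop of R₁ from ν₁ = 10 kHz to ν₂ = 100 kHz. Two
definitions coexist:

- **data mode** (default for profiles): log-log linear interpolation
  between the nearest measured points;
- **model mode:** evaluate the fitted power law, giving the closed form
  ξ = 100·(1 − (ν₂/ν₁)^(−α)), e.g. 49.9 ≈ 50 % at α = 0.30 over one decade.

Data mode is the default because the published per-sample ξ values are not
the model-mode transform of the printed α (e.g. a sample with α = 0.30
prints ξ = 48 where model mode gives 49.9): they were evidently read off the
measured points. Model mode is kept for analytic work and is what the
acceptance script reports.

## Cohort summaries and the report layer

Group means are unweighted arithmetic means over samples; dispersion is the
**population** standard deviation (divisor n). That choice reproduces the
printed ±4 on the reference-group ξ (sample SD would give 5). The printed
table is not fully self-consistent here: the tumor-group amplitude-ratio
spread matches the sample SD instead, and the ± values printed on the
average R₂ rows (±0.2, ±0.3) are far smaller than any standard deviation of
the per-sample values — they look like propagated fit uncertainties. The package prints the population SD throughout and leaves
the discrepancy documented here. Likewise three printed per-row rate ratios
differ by 0.1 from the quotient of the printed R₂ columns (computed upstream
from unrounded rates); the fixture stores the printed values verbatim and
the tests assert exactly that pattern.

Rounding happens only at the report layer: α to 2 decimals, ξ and r to
integer percent, rates to 3 significant digits, ratios to 1 decimal.
Everything upstream carries full precision.

Averaged reference/tumor ratio profiles (`average_ratio()`) exclude cases
only via an explicit id list — mirroring the published exclusion of the one
adenocarcinoma case whose ratio inverts — never by automatic outlier
detection.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 9 patients with a
paired tumor + reference sample each; α ~ U(0.27, 0.33); rate ratio
~ U(1.9, 4.9); amplitude ratio ~ U(0.19, 0.88), always < 1; a 4 s
saturation-recovery window; 1000-echo CPMG trains; 25 log-spaced dispersion
frequencies over 10 kHz–10 MHz plus the 18.7 MHz point; reference
dispersion amplitudes 1.15× their paired tumor's.

Values the source data do not pin down were fixed once, on physical
grounds:

- `r1_ref_range = c(3, 5)` s⁻¹ at 1 MHz, chosen so the implied
  R₁(18.7 MHz) ≈ 1.2–2.1 s⁻¹ is consistent with the published
  R₂,slow and R₂,slow/R₁ columns;
- R₂,slow is drawn as U(1.7, 6.1) × R₁(18.7 MHz) — the observed span of
  that quotient — which enforces the R₂,slow ≥ R₁ bound *by construction*;
- echo spacing 1 ms (not stated in the source), so 1000 echoes span ≈ 5
  slow time constants for rates of a few s⁻¹; configurable;
- 25 grid points, a typical FFC profile density;
- three Lorentzian quadrupole peaks at 2.2, 2.8 and 3.5 MHz (two spectral
  groups, within the 2–4 MHz band), heights ≤ 10 % of the local power-law
  rate — purely phenomenological, matching only the qualitative
  description of weak QRE;
- noise is multiplicative-relative on profile rates (3 %, matching how
  uncertainty enters a rate estimated from a magnetization curve) and
  additive on time-domain signals (0.5 % of the initial amplitude).

The generator does **not** emulate instrument physics (pre-polarization
switching, field ramps, scan averaging beyond its effect on σ), temperature
dependence (37 °C is metadata), partial-volume or exchange effects, more
than two decay components, or any systematic (non-Gaussian, correlated)
noise. Passing parameter-recovery tests therefore demonstrates the
correctness of the estimators under the assumed signal model, not their
robustness to every artefact of real tissue data — the real-data claims
that depend on the deposited raw measurements are outside what a simulation
can verify.

## Validation problem sizes

The test suite validates at the study's own scale: paired cohorts of 9
patients (18 samples), 1000-echo decays, 25-point profiles; bias of the
dispersion exponent is checked over 200 simulated profiles; the power-law
fitter is cross-checked against an independent brute-force SSR minimization
on a 2001 × 2001 (α, r1_at_ref) lattice, where the lattice SSR is evaluated
in closed form per α so no nonlinear optimizer is involved on the oracle
side.

## Known limitations

- Exactly two decay components; no inverse-Laplace / continuous T₂
  spectrum.
- Quadrupole peaks are masked, never fitted; quantitative QRE theory is out
  of scope.
- The degenerate-flag and AICc thresholds are calibrated to this noise
  regime (high-SNR, 1000-echo decays); very noisy or short decays may need
  a different `threshold`.
- Data-mode ξ depends mildly on grid density through interpolation; the
  published choice between nearest-point and interpolated evaluation is
  undocumented, and log-log interpolation was chosen because it is exact on
  a power law.
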