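# relaxometry

Analysis of low-field ¹H NMR relaxation data from tissue samples: power-law
fitting of spin–lattice dispersion profiles, bi-exponential decomposition of
spin–spin (CPMG) decays, and the derived per-sample markers used to compare
tumor against peri-tumoral reference tissue.

## The problem and who this is for

Fast-field-cycling (FFC) NMR relaxometry measures the spin–lattice
relaxation rate R₁ as a function of the proton resonance frequency ν —
here 10 kHz to 10 MHz, complemented by spin–lattice and spin–spin
measurements at 18.7 MHz on a time-domain relaxometer. For heterogeneous
systems such as tissue, the frequency dependence of R₁ probes slow
macromolecular and bound-water dynamics that single-field MRI cannot see.
This package is for researchers analysing such data (or validating analysis
pipelines for it) who need reproducible fits and cohort-level summaries
rather than one-off spreadsheet arithmetic.

## Models

Spin–lattice dispersion follows a power law over the whole measured range:

    R1(ν) = C ν^(−α)

fitted here in the unit-stable anchored form
`R1(ν) = r1_at_ref · (ν/ν_ref)^(−α)` with ν_ref = 1 MHz (`C` is recoverable
as `r1_at_ref · ν_ref^α`). For lung tissue α ≈ 0.3. The spin–spin decay at
18.7 MHz is bi-exponential:

    M(t) = A_slow exp(−R2,slow t) + A_fast exp(−R2,fast t)

with A_fast/A_slow always below 1. Saturation-recovery curves are
single-exponential, `M(t) = M0 (1 − exp(−R1 t))`.

Derived per-sample markers:

- **α** — power-law exponent of the dispersion;
- **ξ** — percent drop of R₁ from 10 kHz to 100 kHz,
  `ξ = 100·(R1(ν₁) − R1(ν₂))/R1(ν₁)`; in model mode
  `ξ = 100·(1 − (ν₂/ν₁)^(−α))`, ≈ 50 % for α = 0.3 over one decade;
- **r = 100·A_fast/A_slow** — amplitude ratio of the two spin–spin pools;
- **R₂,fast/R₂,slow** — rate ratio (observed range 1.9–4.9);
- **R₂,slow/R₁** at 18.7 MHz — must be ≥ 1 on physical grounds; values
  below 1 are flagged.

A synthetic cohort generator produces dispersion profiles (optionally with
quadrupole-peak enhancements in the 2–4 MHz band), recovery curves and CPMG
decays with known ground truth, so that every fitting stage is validated by
parameter recovery.

## Worked example

```r
library(relaxometry)

cfg <- sim_config(n_patients = 3, seed = 42)   # paired tumor + reference
cohort <- generate_cohort(cfg)

gt <- cohort$ground_truth
rows <- lapply(gt$sample_id, function(id) {
  i <- match(id, gt$sample_id)
  marker_set(id, gt$group[i],
             fit_dispersion_power_law(cohort$profiles[[id]]),
             fit_decay_biexp(cohort$decays[[id]]),
             profile = cohort$profiles[[id]])
})
tab <- build_marker_table(do.call(rbind, rows))
write_marker_report(tab, "markers.csv", text_path = "markers.txt")
```

The rounded report (`markers.txt`) for this seed reads:

```
  sample_id     group alpha xi r2_slow r2_fast amp_ratio rate_ratio r2slow_over_r1
1    P1 (t)     tumor  0.33 55    5.47    24.2        64        4.4            3.0
2    P1 (r) reference  0.29 51   11.40    26.1        64        2.3            5.2
3    P2 (t)     tumor  0.30 46    8.99    43.8        37        4.9            4.8
4    P2 (r) reference  0.30 49   12.50    65.9        26        5.3            5.9
5    P3 (t)     tumor  0.31 52    9.42    21.6        78        2.3            5.9
6    P3 (r) reference  0.32 52    3.61    12.3        46        3.4            2.0
7  Avg. (t)     tumor  0.31 51    7.96    29.9        59        3.9            4.5
8  Avg. (r) reference  0.31 51    9.16    34.8        45        3.7            4.4
```

Each row is one sample: `alpha` is the dispersion exponent (all near 0.3),
`xi` the percent drop of R₁ over the 10–100 kHz decade (≈ 50 % at α = 0.3),
`r2_slow`/`r2_fast` the two CPMG rates in s⁻¹, `amp_ratio` the fast/slow
amplitude ratio in percent (always < 100), `rate_ratio` their quotient and
`r2slow_over_r1` the physicality marker (≥ 1). `Avg.` rows are unrounded
group means, rounded only for display. A single fit prints as:

```r
fit_dispersion_power_law(cohort$profiles[["P1 (t)"]])
#> <power_law_fit> alpha = 0.3301 (se 0.0047), R1(1 MHz) = 4.798 1/s, R2 = 0.99681
compute_xi(.Last.value)
#> [1] 53.24072
```

The published 19-sample lung marker table ships as a fixture:
`load_published_markers()`.

A command-line pipeline is available as `exec/relaxcli` (or via
`cli_run()`):

```sh
relaxcli simulate --out data --seed 7
relaxcli fit --in data --out fits --exclude-band 2:4
relaxcli markers --in data --fits fits/fits.csv --out report --exclude P7
```

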