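## Synthetic relaxometry-signal generator. Emulates the statistical structure
## the analysis assumes: power-law R1 dispersion over 10 kHz-10 MHz plus an
## 18.7 MHz point, optional quadrupole-peak enhancements in the 2-4 MHz band,
## single-exponential saturation-recovery curves, bi-exponential CPMG decays
## with amplitude ratio below 1, and additive Gaussian noise. Every sample
## carries its ground truth so parameter recovery can be scored exactly.

#' Simulation configuration for a synthetic relaxometry cohort
#'
#' Defaults reflect the lung-tissue study conditions: nine patients with a
#' paired tumor + peri-tumoral (reference) sample each; power-law exponents
#' in 0.27--0.33; spin--spin rate ratios in 1.9--4.9 and amplitude ratios in
#' 0.19--0.88 (always below 1); a 4 s saturation-recovery window; CPMG
#' trains of 1000 echoes; dispersion grids of 25 log-spaced frequencies over
#' 10 kHz--10 MHz plus the 18.7 MHz point; 3 % relative noise on profile
#' rates and additive noise of 0.5 % of the initial amplitude on decays.
#'
#' The slow spin--spin rate is drawn as a multiple (1.7--6.1) of the model
#' R1 at 18.7 MHz, so every generated sample satisfies the physical bound
#' R2,slow >= R1. The reference sample of each pair exceeds its tumor's
#' dispersion amplitude by `ref_factor` (1.15 by default).
#'
#' @param n_patients Number of patients.
#' @param paired One tumor plus one reference sample per patient.
#' @param alpha_range Range of the power-law exponent.
#' @param r1_ref_range Range of tumor R1 at 1 MHz, in 1/s.
#' @param ref_factor Multiplier taking a tumor's `r1_at_ref` to its paired
#'   reference sample.
#' @param rate_ratio_range Range of R2,fast/R2,slow.
#' @param amp_ratio_range Range of Afast/Aslow (as a fraction, below 1).
#' @param r2s_over_r1_range Range of R2,slow / R1(18.7 MHz).
#' @param profile_noise Relative (multiplicative) Gaussian noise sigma on
#'   profile rates.
#' @param decay_noise Additive Gaussian noise sigma on CPMG decays, as a
#'   fraction of the initial amplitude.
#' @param recovery_noise Additive noise sigma on recovery curves, as a
#'   fraction of the equilibrium magnetization.
#' @param recovery_window Saturation-recovery observation window in s.
#' @param recovery_points Points per recovery curve.
#' @param n_echoes CPMG echoes per decay.
#' @param echo_spacing Echo spacing in s. Not an acquisition constant of the
#'   study; the 1 ms default makes 1000 echoes span roughly 5 slow time
#'   constants for rates of a few 1/s.
#' @param freq_min,freq_max Dispersion grid limits in Hz.
#' @param n_freq Log-spaced grid points between the limits.
#' @param hf_frequency Extra high-field point in Hz (18.7 MHz).
#' @param qre Add quadrupole peaks to the dispersion profiles.
#' @param qre_height_frac Peak height as a fraction of the local power-law
#'   R1.
#' @param seed Master seed; all per-sample streams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 9,
                       paired = TRUE,
                       alpha_range = c(0.27, 0.33),
                       r1_ref_range = c(3, 5),
                       ref_factor = 1.15,
                       rate_ratio_range = c(1.9, 4.9),
                       amp_ratio_range = c(0.19, 0.88),
                       r2s_over_r1_range = c(1.7, 6.1),
                       profile_noise = 0.03,
                       decay_noise = 0.005,
                       recovery_noise = 0.01,
                       recovery_window = 4,
                       recovery_points = 32,
                       n_echoes = 1000,
                       echo_spacing = 1e-3,
                       freq_min = 1e4,
                       freq_max = 1e7,
                       n_freq = 25,
                       hf_frequency = 18.7e6,
                       qre = FALSE,
                       qre_height_frac = 0.08,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), paired = isTRUE(paired),
              alpha_range = alpha_range, r1_ref_range = r1_ref_range,
              ref_factor = ref_factor, rate_ratio_range = rate_ratio_range,
              amp_ratio_range = amp_ratio_range,
              r2s_over_r1_range = r2s_over_r1_range,
              profile_noise = profile_noise, decay_noise = decay_noise,
              recovery_noise = recovery_noise,
              recovery_window = recovery_window,
              recovery_points = as.integer(recovery_points),
              n_echoes = as.integer(n_echoes), echo_spacing = echo_spacing,
              freq_min = freq_min, freq_max = freq_max,
              n_freq = as.integer(n_freq), hf_frequency = hf_frequency,
              qre = isTRUE(qre), qre_height_frac = qre_height_frac,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_range <- function(r, name, lo = -Inf) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2] || r[1] < lo)
      config_error(sprintf("invalid %s", name))
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 1)
    config_error("n_patients must be >= 1")
  chk_range(cfg$alpha_range, "alpha_range", lo = 0)
  chk_range(cfg$r1_ref_range, "r1_ref_range", lo = 0)
  chk_range(cfg$rate_ratio_range, "rate_ratio_range", lo = 1)
  chk_range(cfg$amp_ratio_range, "amp_ratio_range", lo = 0)
  if (cfg$amp_ratio_range[2] >= 1)
    config_error("amp_ratio_range must stay below 1 (Afast < Aslow)")
  chk_range(cfg$r2s_over_r1_range, "r2s_over_r1_range", lo = 1)
  for (f in c("profile_noise", "decay_noise", "recovery_noise"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      config_error(sprintf("%s must be >= 0", f))
  if (cfg$ref_factor <= 0) config_error("ref_factor must be > 0")
  if (cfg$recovery_window <= 0 || cfg$recovery_points < 8)
    config_error("recovery window/points invalid")
  if (cfg$n_echoes < 16 || cfg$echo_spacing <= 0)
    config_error("CPMG echo settings invalid")
  if (cfg$freq_min <= 0 || cfg$freq_min >= cfg$freq_max || cfg$n_freq < 4)
    config_error("frequency grid invalid")
  if (is.na(cfg$seed)) config_error("seed must be an integer")
  invisible(cfg)
}

## Deterministic per-sample substream seeds derived from the master seed;
## kept below 2^31 - 1.
substream_seed <- function(master, index, stream = 0L) {
  as.integer((as.double(master) + 104729 * index + 7919 * stream) %%
               .Machine$integer.max)
}

## Default quadrupole-peak set: two groups of Lorentzian peaks inside the
## 2-4 MHz band (a purely phenomenological stand-in for the 14N transition
## frequencies), with heights tied to the local power-law rate.
default_qre_peaks <- function(gt, height_frac) {
  centers <- c(2.2e6, 2.8e6, 3.5e6)
  widths <- c(0.15e6, 0.15e6, 0.2e6)
  local_r1 <- gt$r1_at_ref * (centers / 1e6)^(-gt$alpha)
  data.frame(center = centers, width = widths,
             height = height_frac * local_r1)
}

#' Additive quadrupole-peak contribution to R1
#'
#' Sum of Lorentzian bumps, `sum(height / (1 + ((nu - center)/width)^2))`,
#' modelling the frequency-specific relaxation enhancement where the proton
#' Larmor frequency matches a 14N quadrupole transition. Purely
#' phenomenological: each peak attains exactly `height` at its center and
#' vanishes with an empty peak list.
#'
#' @param frequency Frequencies in Hz, `> 0` (vectorized).
#' @param peaks Data frame with columns `center`, `width`, `height`
#'   (Hz, Hz, 1/s), or NULL/empty for no peaks.
#' @return Additive R1 contribution in 1/s.
#' @export
qre_peak_term <- function(frequency, peaks) {
  if (any(frequency <= 0)) input_error("frequency must be > 0")
  if (is.null(peaks) || !nrow(peaks)) return(rep(0, length(frequency)))
  if (any(peaks$width <= 0) || any(peaks$height < 0))
    config_error("QRE peak widths must be > 0 and heights >= 0")
  out <- rep(0, length(frequency))
  for (i in seq_len(nrow(peaks))) {
    out <- out + peaks$height[i] /
      (1 + ((frequency - peaks$center[i]) / peaks$width[i])^2)
  }
  out
}

#' Draw ground-truth parameters for a synthetic cohort
#'
#' Deterministic given the master seed. Paired samples share a patient id;
#' each reference sample's dispersion amplitude exceeds its tumor's by
#' `ref_factor` while alpha and the spin--spin parameters are drawn
#' independently per sample. `r2_slow` is a uniform multiple of the model
#' R1(18.7 MHz), enforcing R2,slow >= R1 by construction.
#'
#' @param config A [sim_config()].
#' @return Data frame of class `ground_truth`: one row per sample with
#'   `sample_id`, `patient`, `group`, `alpha`, `r1_at_ref`, `r2_slow`,
#'   `r2_fast`, `a_slow`, `a_fast`, `seed` (per-sample substream).
#' @export
sample_cohort_params <- function(config) {
  validate_sim_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  groups <- if (config$paired) c("tumor", "reference") else "tumor"
  rows <- list()
  k <- 0L
  for (p in seq_len(config$n_patients)) {
    runif_in <- function(r) stats::runif(1, r[1], r[2])
    r1_tumor <- runif_in(config$r1_ref_range)
    for (g in groups) {
      k <- k + 1L
      alpha <- runif_in(config$alpha_range)
      r1_ref <- if (g == "tumor") r1_tumor else r1_tumor * config$ref_factor
      r1_hf <- r1_ref * (config$hf_frequency / 1e6)^(-alpha)
      r2_slow <- runif_in(config$r2s_over_r1_range) * r1_hf
      r2_fast <- r2_slow * runif_in(config$rate_ratio_range)
      r <- runif_in(config$amp_ratio_range)
      rows[[k]] <- data.frame(
        sample_id = sprintf("P%d (%s)", p, substr(g, 1, 1)),
        patient = sprintf("P%d", p), group = g,
        alpha = alpha, r1_at_ref = r1_ref,
        r2_slow = r2_slow, r2_fast = r2_fast,
        a_slow = 1 / (1 + r), a_fast = r / (1 + r),
        seed = substream_seed(config$seed, k),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ground_truth", "data.frame")
  out
}

## save/restore the global RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

dispersion_grid <- function(config) {
  grid <- exp(seq(log(config$freq_min), log(config$freq_max),
                  length.out = config$n_freq))
  sort(unique(c(grid, config$hf_frequency)))
}

#' Generate one sample's dispersion profile
#'
#' The true rate is the power law plus the sample's quadrupole-peak term
#' (when QRE is enabled); the observed rate is the truth times
#' `(1 + eps)` with `eps ~ N(0, profile_noise^2)`, i.e. multiplicative
#' relative noise, which is how uncertainty enters a rate estimated from a
#' magnetization curve. The grid always contains the 18.7 MHz point. In
#' `with_curves` mode a noisy saturation-recovery curve is emitted per
#' frequency so the full curve-to-profile pipeline can be exercised.
#'
#' @param gt One row of [sample_cohort_params()] output (data frame or
#'   list).
#' @param config A [sim_config()].
#' @param seed Substream seed; defaults to the sample's `seed` field.
#' @param with_curves Also return per-frequency recovery curves.
#' @return A [dispersion_profile()], or when `with_curves = TRUE` a list
#'   with elements `profile` and `curves`.
#' @export
generate_dispersion <- function(gt, config, seed = gt$seed,
                                with_curves = FALSE) {
  validate_sim_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 1L, stream = 1L))
  nu <- dispersion_grid(config)
  model <- power_law_fit(alpha = gt$alpha, r1_at_ref = gt$r1_at_ref)
  truth <- power_law_r1(nu, model)
  if (config$qre)
    truth <- truth + qre_peak_term(
      nu, default_qre_peaks(gt, config$qre_height_frac))
  observed <- truth * (1 + stats::rnorm(length(nu), 0, config$profile_noise))
  observed <- pmax(observed, 1e-6 * truth)  # rates stay positive
  profile <- dispersion_profile(gt$sample_id, nu, observed,
                                r1_uncertainties = config$profile_noise * truth)
  if (!with_curves) return(profile)
  curves <- lapply(seq_along(nu), function(i) {
    tt <- seq(0, config$recovery_window, length.out = config$recovery_points)
    m <- monoexp_recovery(tt, 1, truth[i]) +
      stats::rnorm(length(tt), 0, config$recovery_noise)
    recovery_curve(tt, m, nu[i])
  })
  list(profile = profile, curves = curves)
}

#' Generate one sample's CPMG decay
#'
#' Echo-time grid `echo_spacing * (1..n_echoes)`; signal is the
#' bi-exponential forward model plus additive Gaussian noise with sigma
#' equal to `decay_noise` times the initial amplitude `a_slow + a_fast`.
#'
#' @inheritParams generate_dispersion
#' @return A [decay_curve()] at the high-field frequency.
#' @export
generate_cpmg_decay <- function(gt, config, seed = gt$seed) {
  validate_sim_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 1L, stream = 2L))
  tt <- config$echo_spacing * seq_len(config$n_echoes)
  fit <- bi_exp_fit(r2_slow = gt$r2_slow, r2_fast = gt$r2_fast,
                    a_slow = gt$a_slow, a_fast = gt$a_fast)
  sigma <- config$decay_noise * (gt$a_slow + gt$a_fast)
  sig <- biexp_magnetization(tt, fit) +
    stats::rnorm(length(tt), 0, sigma)
  decay_curve(tt, sig, config$hf_frequency)
}

#' Generate a full synthetic cohort
#'
#' Draws ground-truth parameters, then one dispersion profile and one CPMG
#' decay per sample, all reproducible from `(config, seed)`. With `dir` the
#' bundle is also written to disk (profiles/ and decays/ CSV files, a JSON
#' manifest, and a ground-truth CSV).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return A list of class `cohort` with `config`, `ground_truth`,
#'   `manifest` (sample_id/patient/group), `profiles` and `decays` (named
#'   lists keyed by sample_id).
#' @export
generate_cohort <- function(config, dir = NULL) {
  gt <- sample_cohort_params(config)
  profiles <- list()
  decays <- list()
  for (i in seq_len(nrow(gt))) {
    row <- gt[i, ]
    profiles[[row$sample_id]] <- generate_dispersion(row, config)
    decays[[row$sample_id]] <- generate_cpmg_decay(row, config)
  }
  manifest <- gt[, c("sample_id", "patient", "group")]
  bundle <- structure(list(config = config, ground_truth = gt,
                           manifest = manifest, profiles = profiles,
                           decays = decays),
                      class = "cohort")
  if (!is.null(dir)) write_cohort(bundle, dir)
  bundle
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples (%d patients, %s), seed %d\n",
              nrow(x$ground_truth), x$config$n_patients,
              if (x$config$paired) "paired" else "tumor only",
              x$config$seed))
  invisible(x)
}
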