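#' @keywords internal
"_PACKAGE"

## Condition helpers shared across modules. Each error carries a class so the
## CLI can map it to an exit code and tests can assert on the failure mode.
relax_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "relax_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

input_error  <- function(msg, ...) relax_error("relax_input_error", msg, ...)
config_error <- function(msg, ...) relax_error("relax_config_error", msg, ...)
parse_error  <- function(msg, ...) relax_error("relax_parse_error", msg, ...)
fit_error    <- function(msg, ...) relax_error("relax_fit_error", msg, ...)

#' Dispersion profile: R1 versus Larmor frequency for one sample
#'
#' Container for a nuclear magnetic relaxation dispersion (NMRD) profile:
#' spin--lattice relaxation rates `R1` measured at a set of proton resonance
#' frequencies, typically 10 kHz--10 MHz from a fast-field-cycling
#' relaxometer plus a high-field point (18.7 MHz here).
#'
#' @param sample_id Character scalar identifying the sample.
#' @param frequencies Numeric vector of resonance frequencies in Hz,
#'   strictly increasing and positive.
#' @param r1_values Numeric vector of spin--lattice rates in 1/s, positive,
#'   same length as `frequencies`.
#' @param r1_uncertainties Optional numeric vector of 1-sigma uncertainties
#'   on `r1_values`, in 1/s.
#' @return An object of class `dispersion_profile`.
#' @export
dispersion_profile <- function(sample_id, frequencies, r1_values,
                               r1_uncertainties = NULL) {
  frequencies <- as.numeric(frequencies)
  r1_values <- as.numeric(r1_values)
  if (length(frequencies) != length(r1_values))
    input_error("frequencies and r1_values must have equal length")
  if (anyNA(frequencies) || anyNA(r1_values) ||
      !all(is.finite(frequencies)) || !all(is.finite(r1_values)))
    input_error("frequencies and r1_values must be finite")
  if (any(frequencies <= 0)) input_error("frequencies must be > 0")
  if (is.unsorted(frequencies, strictly = TRUE))
    input_error("frequencies must be strictly increasing")
  if (any(r1_values <= 0)) input_error("r1_values must be > 0")
  if (!is.null(r1_uncertainties)) {
    r1_uncertainties <- as.numeric(r1_uncertainties)
    if (length(r1_uncertainties) != length(frequencies))
      input_error("r1_uncertainties length mismatch")
    if (any(!is.finite(r1_uncertainties)) || any(r1_uncertainties < 0))
      input_error("r1_uncertainties must be finite and >= 0")
  }
  structure(list(sample_id = as.character(sample_id),
                 frequencies = frequencies, r1_values = r1_values,
                 r1_uncertainties = r1_uncertainties),
            class = "dispersion_profile")
}

#' @export
print.dispersion_profile <- function(x, ...) {
  cat(sprintf("<dispersion_profile> %s: %d points, %.3g kHz - %.4g MHz\n",
              x$sample_id, length(x$frequencies),
              min(x$frequencies) / 1e3, max(x$frequencies) / 1e6))
  invisible(x)
}

new_curve <- function(times, signal, frequency, class, min_points,
                      allow_zero_time) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal))
    input_error("times and signal must have equal length")
  if (length(times) < min_points)
    input_error(sprintf("curve needs at least %d points", min_points))
  if (!all(is.finite(times)) || !all(is.finite(signal)))
    input_error("times and signal must be finite")
  if (is.unsorted(times, strictly = TRUE))
    input_error("times must be strictly increasing")
  lo <- if (allow_zero_time) 0 else .Machine$double.xmin
  if (times[1] < lo)
    input_error(if (allow_zero_time) "times must be >= 0" else "times must be > 0")
  if (!is.numeric(frequency) || length(frequency) != 1 || frequency <= 0)
    input_error("frequency must be a positive scalar in Hz")
  structure(list(times = times, signal = signal, frequency = frequency),
            class = class)
}

#' Saturation-recovery curve
#'
#' Longitudinal magnetization versus recovery time from a saturation-recovery
#' experiment, starting at zero magnetization and recovering towards
#' equilibrium with rate R1.
#'
#' @param times Recovery delays in seconds, strictly increasing, `>= 0`;
#'   at least 8 points.
#' @param signal Magnetization in arbitrary units.
#' @param frequency Resonance frequency in Hz at which the curve was acquired.
#' @return An object of class `recovery_curve`.
#' @export
recovery_curve <- function(times, signal, frequency) {
  new_curve(times, signal, frequency, "recovery_curve",
            min_points = 8, allow_zero_time = TRUE)
}

#' CPMG decay curve
#'
#' Transverse magnetization at the echo maxima of a Carr--Purcell--Meiboom--Gill
#' train, decaying with the spin--spin rate(s) R2.
#'
#' @param times Echo times in seconds, strictly increasing, `> 0`; at least
#'   16 points.
#' @param signal Magnetization in arbitrary units.
#' @param frequency Resonance frequency in Hz.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(times, signal, frequency) {
  new_curve(times, signal, frequency, "decay_curve",
            min_points = 16, allow_zero_time = FALSE)
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %d points over %.3g s @ %.4g MHz\n",
              length(x$times), max(x$times), x$frequency / 1e6))
  invisible(x)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d echoes over %.3g s @ %.4g MHz\n",
              length(x$times), max(x$times), x$frequency / 1e6))
  invisible(x)
}

#' Power-law dispersion model parameters
#'
#' Parameters of the power-law frequency dependence of the spin--lattice
#' rate, `R1(nu) = r1_at_ref * (nu / ref_frequency)^(-alpha)`. The
#' conventional pre-factor `C` of `R1 = C nu^-alpha` has awkward units
#' (`s^(alpha-1)`); anchoring the rate at a reference frequency (1 MHz by
#' default) keeps the parameterization unit-clean. `C` is recoverable as
#' `r1_at_ref * ref_frequency^alpha`.
#'
#' @param alpha Dimensionless power-law exponent.
#' @param r1_at_ref Model R1 at `ref_frequency`, in 1/s, `> 0`.
#' @param ref_frequency Reference frequency in Hz (default 1 MHz).
#' @param alpha_stderr Standard error of `alpha` (NA if not estimated).
#' @param r_squared Coefficient of determination of the fit on the linear
#'   scale (NA for a hand-constructed model).
#' @return An object of class `power_law_fit`.
#' @export
power_law_fit <- function(alpha, r1_at_ref, ref_frequency = 1e6,
                          alpha_stderr = NA_real_, r_squared = NA_real_) {
  if (!is.finite(alpha)) input_error("alpha must be finite")
  if (!is.finite(r1_at_ref) || r1_at_ref <= 0)
    input_error("r1_at_ref must be > 0")
  if (ref_frequency <= 0) input_error("ref_frequency must be > 0")
  if (is.finite(r_squared) && r_squared > 1 + 1e-12)
    input_error("r_squared must be <= 1")
  structure(list(alpha = alpha, r1_at_ref = r1_at_ref,
                 ref_frequency = ref_frequency,
                 alpha_stderr = alpha_stderr, r_squared = r_squared),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.4f (se %.2g), R1(%.3g MHz) = %.4g 1/s, R2 = %.5g\n",
              x$alpha, x$alpha_stderr, x$ref_frequency / 1e6, x$r1_at_ref,
              x$r_squared))
  invisible(x)
}

#' Mono-exponential relaxation fit parameters
#'
#' @param rate Relaxation rate (R1 or R2) in 1/s, `> 0`.
#' @param amplitude Equilibrium magnetization M0 (recovery) or initial
#'   amplitude (decay), arbitrary units, `> 0`.
#' @param rate_stderr Standard error of `rate` in 1/s.
#' @param r_squared Coefficient of determination.
#' @param kind `"recovery"` or `"decay"`; which mono-exponential shape the
#'   parameters describe.
#' @return An object of class `mono_exp_fit`.
#' @export
mono_exp_fit <- function(rate, amplitude, rate_stderr = NA_real_,
                         r_squared = NA_real_,
                         kind = c("recovery", "decay")) {
  kind <- match.arg(kind)
  if (!is.finite(rate) || rate <= 0) input_error("rate must be > 0")
  if (!is.finite(amplitude) || amplitude <= 0)
    input_error("amplitude must be > 0")
  structure(list(rate = rate, amplitude = amplitude,
                 rate_stderr = rate_stderr, r_squared = r_squared,
                 kind = kind),
            class = "mono_exp_fit")
}

#' @export
print.mono_exp_fit <- function(x, ...) {
  cat(sprintf("<mono_exp_fit:%s> rate = %.4g 1/s (se %.2g), amplitude = %.4g, R2 = %.5g\n",
              x$kind, x$rate, x$rate_stderr, x$amplitude, x$r_squared))
  invisible(x)
}

#' Bi-exponential spin--spin decay parameters
#'
#' Parameters of `M(t) = a_slow exp(-r2_slow t) + a_fast exp(-r2_fast t)`.
#' The constructor canonicalizes the component labels so that
#' `r2_slow <= r2_fast` regardless of input order.
#'
#' @param r2_slow,r2_fast Spin--spin rates of the two components in 1/s.
#' @param a_slow,a_fast Component amplitudes in arbitrary units;
#'   `a_slow > 0`, `a_fast >= 0` after canonicalization.
#' @param r2_slow_stderr,r2_fast_stderr,a_slow_stderr,a_fast_stderr
#'   Standard errors of the corresponding parameters.
#' @param r_squared Coefficient of determination.
#' @param degenerate Logical flag: `TRUE` when the two components are not
#'   distinguishable (rate ratio below the degeneracy threshold or a
#'   vanishing fast amplitude).
#' @return An object of class `bi_exp_fit`.
#' @export
bi_exp_fit <- function(r2_slow, r2_fast, a_slow, a_fast,
                       r2_slow_stderr = NA_real_, r2_fast_stderr = NA_real_,
                       a_slow_stderr = NA_real_, a_fast_stderr = NA_real_,
                       r_squared = NA_real_, degenerate = FALSE) {
  if (!all(is.finite(c(r2_slow, r2_fast, a_slow, a_fast))))
    input_error("bi-exponential parameters must be finite")
  if (r2_slow <= 0 || r2_fast <= 0) input_error("rates must be > 0")
  if (a_slow < 0 || a_fast < 0) input_error("amplitudes must be >= 0")
  if (r2_slow > r2_fast) {  # swap labels so 'slow' is the slower rate
    tmp <- r2_slow; r2_slow <- r2_fast; r2_fast <- tmp
    tmp <- a_slow; a_slow <- a_fast; a_fast <- tmp
    tmp <- r2_slow_stderr; r2_slow_stderr <- r2_fast_stderr; r2_fast_stderr <- tmp
    tmp <- a_slow_stderr; a_slow_stderr <- a_fast_stderr; a_fast_stderr <- tmp
  }
  if (a_slow <= 0)
    input_error("a_slow must be > 0 after canonicalization")
  structure(list(r2_slow = r2_slow, r2_fast = r2_fast,
                 a_slow = a_slow, a_fast = a_fast,
                 r2_slow_stderr = r2_slow_stderr,
                 r2_fast_stderr = r2_fast_stderr,
                 a_slow_stderr = a_slow_stderr,
                 a_fast_stderr = a_fast_stderr,
                 r_squared = r_squared,
                 degenerate = isTRUE(degenerate)),
            class = "bi_exp_fit")
}

#' @export
print.bi_exp_fit <- function(x, ...) {
  cat(sprintf(
    "<bi_exp_fit> R2slow = %.4g, R2fast = %.4g 1/s; Aslow = %.4g, Afast = %.4g; R2 = %.5g%s\n",
    x$r2_slow, x$r2_fast, x$a_slow, x$a_fast, x$r_squared,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Evaluate the power-law dispersion model
#'
#' `R1(nu) = r1_at_ref * (nu / ref_frequency)^(-alpha)`: the model rate is
#' strictly decreasing in frequency for `alpha > 0` and log-log linear with
#' slope `-alpha`.
#'
#' @param frequency Frequencies in Hz, all `> 0` (vectorized).
#' @param fit A [power_law_fit()].
#' @return Spin--lattice rates R1 in 1/s.
#' @export
power_law_r1 <- function(frequency, fit) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    input_error("frequency must be > 0")
  fit$r1_at_ref * (frequency / fit$ref_frequency)^(-fit$alpha)
}

#' Evaluate the bi-exponential decay model
#'
#' `M(t) = a_slow exp(-r2_slow t) + a_fast exp(-r2_fast t)`. At `t = 0` the
#' value equals `a_slow + a_fast`; the curve is monotone decreasing.
#'
#' @param time Times in seconds, `>= 0` (vectorized).
#' @param fit A [bi_exp_fit()].
#' @return Magnetization in arbitrary units.
#' @export
biexp_magnetization <- function(time, fit) {
  stopifnot(inherits(fit, "bi_exp_fit"))
  if (any(!is.finite(time)) || any(time < 0))
    input_error("time must be >= 0")
  fit$a_slow * exp(-fit$r2_slow * time) + fit$a_fast * exp(-fit$r2_fast * time)
}

#' Evaluate the saturation-recovery model
#'
#' `M(t) = m0 (1 - exp(-r1 t))`: zero at `t = 0`, approaching the
#' equilibrium magnetization `m0` for long recovery times.
#'
#' @param time Times in seconds, `>= 0` (vectorized).
#' @param m0 Equilibrium magnetization, `> 0`.
#' @param r1 Spin--lattice rate in 1/s, `> 0`.
#' @return Magnetization in arbitrary units.
#' @export
monoexp_recovery <- function(time, m0, r1) {
  if (any(!is.finite(time)) || any(time < 0))
    input_error("time must be >= 0")
  if (!is.finite(m0) || m0 <= 0) input_error("m0 must be > 0")
  if (!is.finite(r1) || r1 <= 0) input_error("r1 must be > 0")
  m0 * (1 - exp(-r1 * time))
}

## Mono-exponential decay (CPMG single-component shape); used by the fitter
## and the model-selection step.
monoexp_decay <- function(time, amplitude, rate) amplitude * exp(-rate * time)
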