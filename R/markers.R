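## Derived per-sample relaxation markers and cohort summaries: the
## low-frequency dispersion drop xi, the rate and amplitude ratios of the two
## spin-spin components, the R2,slow/R1 physicality check, reference/tumor
## ratio profiles, and the tabular report mirroring the study's summary table.

MARKER_COLS <- c("alpha", "xi", "r2_slow", "r2_fast", "amp_ratio",
                 "rate_ratio", "r2slow_over_r1", "r1_at_18_7")

## log-log linear interpolation of R1 at arbitrary frequencies; the query is
## clamped to the grid so a target equal to an endpoint is never rejected by
## floating-point jitter in a log-spaced grid
interp_loglog <- function(frequencies, r1_values, at) {
  at <- pmin(pmax(at, min(frequencies)), max(frequencies))
  exp(stats::approx(log(frequencies), log(r1_values), xout = log(at),
                    rule = 2)$y)
}

#' Low-frequency dispersion drop xi
#'
#' The relative decrease of the spin--lattice rate between two frequencies,
#' `xi = 100 (R1(nu1) - R1(nu2)) / R1(nu1)` in percent. The conventional
#' window is one decade at the low-frequency end, 10 kHz to 100 kHz, where
#' tissue dispersion profiles differ most.
#'
#' In `"data"` mode (default for profiles) R1 at `nu1` and `nu2` is obtained
#' by log-log linear interpolation between the nearest measured points. In
#' `"model"` mode (the only mode for a [power_law_fit()]) the fitted power
#' law is evaluated, giving the closed form
#' `xi = 100 (1 - (nu2/nu1)^-alpha)`, which depends only on alpha and the
#' frequency ratio.
#'
#' @param x A [dispersion_profile()] or [power_law_fit()].
#' @param nu1,nu2 Frequencies in Hz with `nu1 < nu2`; defaults 10 kHz and
#'   100 kHz.
#' @param mode `"data"` or `"model"`; defaults to `"data"` for profiles.
#' @return xi in percent.
#' @export
compute_xi <- function(x, nu1 = 1e4, nu2 = 1e5, mode = c("data", "model")) {
  if (!is.numeric(nu1) || !is.numeric(nu2) || nu1 <= 0 || nu1 >= nu2)
    input_error("need 0 < nu1 < nu2")
  if (inherits(x, "power_law_fit"))
    return(100 * (1 - (nu2 / nu1)^(-x$alpha)))
  mode <- match.arg(mode)
  stopifnot(inherits(x, "dispersion_profile"))
  if (mode == "model") {
    fit <- fit_dispersion_power_law(x)
    return(100 * (1 - (nu2 / nu1)^(-fit$alpha)))
  }
  span <- range(x$frequencies)
  if (nu1 < span[1] * (1 - 1e-9) || nu2 > span[2] * (1 + 1e-9))
    input_error("nu1 and nu2 must lie within the measured frequency span")
  r1 <- interp_loglog(x$frequencies, x$r1_values, c(nu1, nu2))
  100 * (r1[1] - r1[2]) / r1[1]
}

#' Rate ratio of the two spin--spin components
#'
#' `R2,fast / R2,slow`, guaranteed `>= 1` by the canonical component
#' ordering of [bi_exp_fit()].
#'
#' @param fit A [bi_exp_fit()].
#' @return Dimensionless ratio.
#' @export
compute_rate_ratio <- function(fit) {
  stopifnot(inherits(fit, "bi_exp_fit"))
  fit$r2_fast / fit$r2_slow
}

#' Amplitude ratio of the two spin--spin components
#'
#' `r = 100 Afast / Aslow` in percent. Values below 100 mean the faster
#' relaxing pool carries less magnetization than the slower one, as observed
#' throughout lung tissue.
#'
#' @param fit A [bi_exp_fit()].
#' @return Amplitude ratio in percent.
#' @export
compute_amp_ratio <- function(fit) {
  stopifnot(inherits(fit, "bi_exp_fit"))
  if (fit$a_slow <= 0) input_error("a_slow must be > 0")
  100 * fit$a_fast / fit$a_slow
}

#' Ratio of the slow spin--spin rate to the spin--lattice rate
#'
#' `R2,slow / R1` at the high-field frequency. Spin--spin rates can never be
#' lower than the corresponding spin--lattice rates, so a ratio below 1 is
#' unphysical; such a value raises a warning and is flagged via the
#' `"physical"` attribute rather than rejected, so that questionable fits
#' remain visible in reports.
#'
#' @param fit A [bi_exp_fit()].
#' @param r1 Spin--lattice rate in 1/s at the same frequency, `> 0`.
#' @return The ratio, with attribute `physical` (`TRUE`/`FALSE`).
#' @export
compute_r2slow_over_r1 <- function(fit, r1) {
  stopifnot(inherits(fit, "bi_exp_fit"))
  if (!is.numeric(r1) || length(r1) != 1 || !is.finite(r1) || r1 <= 0)
    input_error("r1 must be a positive scalar")
  ratio <- fit$r2_slow / r1
  physical <- ratio >= 1
  if (!physical)
    warning(sprintf("R2,slow/R1 = %.3g < 1 is unphysical", ratio),
            call. = FALSE)
  structure(ratio, physical = physical)
}

#' Pointwise reference/tumor ratio of two dispersion profiles
#'
#' `R1_ref(nu) / R1_tumor(nu)` on the part of the reference grid covered by
#' both profiles. When the grids differ the tumor profile is log-log
#' interpolated onto the reference grid.
#'
#' @param reference,tumor [dispersion_profile()] objects with overlapping
#'   frequency ranges.
#' @return A data frame of class `ratio_series` with columns `frequency`
#'   (Hz) and `ratio`, and attributes `reference_id` / `tumor_id`.
#' @export
ratio_profile <- function(reference, tumor) {
  stopifnot(inherits(reference, "dispersion_profile"),
            inherits(tumor, "dispersion_profile"))
  lo <- max(min(reference$frequencies), min(tumor$frequencies))
  hi <- min(max(reference$frequencies), max(tumor$frequencies))
  if (lo > hi) input_error("profiles have no overlapping frequency range")
  keep <- reference$frequencies >= lo & reference$frequencies <= hi
  if (!any(keep)) input_error("no reference grid points inside the overlap")
  nu <- reference$frequencies[keep]
  r1_t <- interp_loglog(tumor$frequencies, tumor$r1_values, nu)
  out <- data.frame(frequency = nu,
                    ratio = reference$r1_values[keep] / r1_t)
  attr(out, "reference_id") <- reference$sample_id
  attr(out, "tumor_id") <- tumor$sample_id
  class(out) <- c("ratio_series", "data.frame")
  out
}

#' Average several reference/tumor ratio series
#'
#' Pointwise arithmetic mean of the ratio series across cases, on the
#' intersection of their frequency grids (series are log-frequency
#' interpolated onto the common grid when grids differ), plus the grand mean
#' over the grid. Cases listed in `exclude` are dropped before averaging;
#' exclusion is always an explicit caller decision, never automatic outlier
#' rejection.
#'
#' @param ratios Named list of `ratio_series` (names are case ids).
#' @param exclude Character vector of case ids to drop.
#' @return A list with `mean_series` (a `ratio_series`), `grand_mean`
#'   (scalar), and `n` (cases averaged).
#' @export
average_ratio <- function(ratios, exclude = character()) {
  if (!length(ratios)) input_error("no ratio series supplied")
  if (is.null(names(ratios)) && length(exclude))
    input_error("ratios must be named to use exclude")
  keep <- if (is.null(names(ratios))) seq_along(ratios)
          else !(names(ratios) %in% exclude)
  ratios <- ratios[keep]
  if (!length(ratios)) input_error("no ratio series left after exclusion")
  lo <- max(vapply(ratios, function(r) min(r$frequency), 0))
  hi <- min(vapply(ratios, function(r) max(r$frequency), 0))
  if (lo > hi) input_error("ratio series have no common frequency range")
  grid <- ratios[[1]]$frequency
  grid <- grid[grid >= lo & grid <= hi]
  if (!length(grid)) input_error("empty common frequency grid")
  mat <- vapply(ratios, function(r) {
    stats::approx(log(r$frequency), r$ratio, xout = log(grid), rule = 1)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  mean_series <- data.frame(frequency = grid, ratio = rowMeans(mat))
  class(mean_series) <- c("ratio_series", "data.frame")
  list(mean_series = mean_series,
       grand_mean = mean(mean_series$ratio),
       n = length(ratios))
}

#' Assemble one sample's marker row
#'
#' Bundles the fitted dispersion and decay parameters of one sample into a
#' one-row data frame mirroring the study's summary table: power-law
#' exponent alpha, dispersion drop xi, the two spin--spin rates, the
#' amplitude ratio r, the rate ratio, and R2,slow/R1 at the high-field
#' frequency.
#'
#' @param sample_id Sample identifier.
#' @param group `"tumor"` or `"reference"`.
#' @param power_fit A [power_law_fit()].
#' @param biexp_fit A [bi_exp_fit()].
#' @param profile Optional [dispersion_profile()]; when given, xi is
#'   computed in data mode from the measured points and R1(18.7 MHz) is
#'   interpolated from the profile, otherwise both come from the power law.
#' @param r1_frequency Frequency in Hz of the spin--lattice rate used in the
#'   R2,slow/R1 marker (default 18.7 MHz).
#' @param xi_nu1,xi_nu2 Frequencies of the xi window (defaults 10/100 kHz).
#' @return One-row data frame with the marker columns.
#' @export
marker_set <- function(sample_id, group = c("tumor", "reference"),
                       power_fit, biexp_fit, profile = NULL,
                       r1_frequency = 18.7e6,
                       xi_nu1 = 1e4, xi_nu2 = 1e5) {
  group <- match.arg(group)
  stopifnot(inherits(power_fit, "power_law_fit"),
            inherits(biexp_fit, "bi_exp_fit"))
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "dispersion_profile"))
    xi <- compute_xi(profile, xi_nu1, xi_nu2, mode = "data")
    span <- range(profile$frequencies)
    r1_hf <- if (r1_frequency >= span[1] && r1_frequency <= span[2])
      interp_loglog(profile$frequencies, profile$r1_values, r1_frequency)
    else power_law_r1(r1_frequency, power_fit)
  } else {
    xi <- compute_xi(power_fit, xi_nu1, xi_nu2)
    r1_hf <- power_law_r1(r1_frequency, power_fit)
  }
  ratio <- suppressWarnings(compute_r2slow_over_r1(biexp_fit, r1_hf))
  data.frame(sample_id = sample_id, group = group,
             alpha = power_fit$alpha, xi = xi,
             r2_slow = biexp_fit$r2_slow, r2_fast = biexp_fit$r2_fast,
             amp_ratio = compute_amp_ratio(biexp_fit),
             rate_ratio = compute_rate_ratio(biexp_fit),
             r2slow_over_r1 = as.numeric(ratio),
             r1_at_18_7 = r1_hf,
             physical = attr(ratio, "physical"),
             stringsAsFactors = FALSE)
}

## population standard deviation (divisor n), matching the dispersion
## convention used for the cohort-average rows
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize a cohort group
#'
#' Unweighted arithmetic mean and population standard deviation of every
#' marker over the samples of one group. Rounding happens only at the
#' report layer.
#'
#' @param markers Data frame of marker rows (see [marker_set()]).
#' @param group `"tumor"` or `"reference"`.
#' @return Data frame with columns `marker`, `mean`, `sd`; attributes
#'   `group` and `n`.
#' @export
summarize_group <- function(markers, group) {
  if (!group %in% c("tumor", "reference"))
    input_error(sprintf("unknown group '%s'", group))
  sub <- markers[markers$group == group, , drop = FALSE]
  if (!nrow(sub)) input_error(sprintf("no samples in group '%s'", group))
  cols <- intersect(MARKER_COLS, names(sub))
  out <- data.frame(marker = cols,
                    mean = vapply(cols, function(cl) mean(sub[[cl]]), 0),
                    sd = vapply(cols, function(cl) pop_sd(sub[[cl]]), 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "group") <- group
  attr(out, "n") <- nrow(sub)
  out
}

#' Build the per-sample marker table with cohort-average rows
#'
#' One row per sample plus, when both groups are present, `Avg. (t)` and
#' `Avg. (r)` rows holding the unrounded group means. Samples with missing
#' fit components are kept and flagged `incomplete` rather than dropped.
#'
#' @param markers Data frame of marker rows from [marker_set()] (possibly
#'   with NA cells for failed fits).
#' @param include_avg Append the group-average rows (default `TRUE`).
#' @return Data frame of class `marker_table`.
#' @export
build_marker_table <- function(markers, include_avg = TRUE) {
  cols <- c("sample_id", "group", MARKER_COLS)
  if (!nrow(markers)) {
    out <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(cols) + 1)),
      c(cols, "incomplete"))
    class(out) <- c("marker_table", "data.frame")
    return(out)
  }
  for (cl in setdiff(cols, names(markers))) markers[[cl]] <- NA_real_
  out <- markers[, cols, drop = FALSE]
  out$incomplete <- !stats::complete.cases(out[, MARKER_COLS])
  if (include_avg) {
    for (g in c("tumor", "reference")) {
      complete <- out[out$group == g & !out$incomplete, , drop = FALSE]
      if (!nrow(complete)) next
      avg <- data.frame(
        sample_id = sprintf("Avg. (%s)", substr(g, 1, 1)), group = g,
        t(vapply(MARKER_COLS, function(cl) mean(complete[[cl]]), 0)),
        incomplete = FALSE, stringsAsFactors = FALSE)
      names(avg) <- c("sample_id", "group", MARKER_COLS, "incomplete")
      out <- rbind(out, avg)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

## Report-layer rounding: alpha to 2 decimals; xi and r to integer percent;
## rates to 3 significant digits; ratios to 1 decimal.
round_marker_table <- function(table) {
  out <- as.data.frame(table)
  out$alpha <- round(out$alpha, 2)
  out$xi <- round(out$xi)
  out$amp_ratio <- round(out$amp_ratio)
  out$r2_slow <- signif(out$r2_slow, 3)
  out$r2_fast <- signif(out$r2_fast, 3)
  out$rate_ratio <- round(out$rate_ratio, 1)
  out$r2slow_over_r1 <- round(out$r2slow_over_r1, 1)
  if ("r1_at_18_7" %in% names(out))
    out$r1_at_18_7 <- signif(out$r1_at_18_7, 3)
  out
}
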