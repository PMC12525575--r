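# Shared fixture builders. Everything is generated in code; seeds are fixed
# so expected values frozen in the tests are reproducible.

log_grid <- function(lo = 1e4, hi = 1e7, n = 25) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# noise-free power-law profile
exact_profile <- function(alpha = 0.30, r1_at_ref = 20, n = 25,
                          id = "exact") {
  nu <- log_grid(n = n)
  dispersion_profile(id, nu, r1_at_ref * (nu / 1e6)^(-alpha))
}

noisy_profile <- function(alpha = 0.30, r1_at_ref = 20, n = 25,
                          sigma = 0.03, seed = 101, id = "noisy") {
  nu <- log_grid(n = n)
  truth <- r1_at_ref * (nu / 1e6)^(-alpha)
  withr::with_seed(seed,
    dispersion_profile(id, nu, truth * (1 + rnorm(n, 0, sigma))))
}

# noise-free bi-exponential CPMG decay
exact_decay <- function(r2_slow = 10.8, r2_fast = 24.1,
                        a_slow = 0.7, a_fast = 0.3,
                        n_echoes = 1000, spacing = 1e-3) {
  tt <- spacing * seq_len(n_echoes)
  fit <- bi_exp_fit(r2_slow, r2_fast, a_slow, a_fast)
  decay_curve(tt, biexp_magnetization(tt, fit), 18.7e6)
}

noisy_decay <- function(r2_slow = 10.8, r2_fast = 24.1,
                        a_slow = 0.7, a_fast = 0.3,
                        sigma = 0.005, seed = 202,
                        n_echoes = 1000, spacing = 1e-3) {
  tt <- spacing * seq_len(n_echoes)
  fit <- bi_exp_fit(r2_slow, r2_fast, a_slow, a_fast)
  withr::with_seed(seed,
    decay_curve(tt, biexp_magnetization(tt, fit) +
                  rnorm(n_echoes, 0, sigma * (a_slow + a_fast)),
                18.7e6))
}

# independent brute-force SSR minimization of the power-law model on an
# (alpha, r1_at_ref) lattice; per alpha the SSR over the r1 lattice is a
# quadratic evaluated in closed form, so no nonlinear optimizer is involved
grid_search_power_law <- function(profile, alpha_grid, r1_grid,
                                  ref_frequency = 1e6) {
  x <- profile$frequencies / ref_frequency
  y <- profile$r1_values
  best <- c(alpha = NA_real_, r1 = NA_real_, ssr = Inf)
  sum_y2 <- sum(y^2)
  for (a in alpha_grid) {
    m <- x^(-a)
    ssr <- sum_y2 - 2 * r1_grid * sum(y * m) + r1_grid^2 * sum(m^2)
    i <- which.min(ssr)
    if (ssr[i] < best["ssr"])
      best <- c(alpha = a, r1 = r1_grid[i], ssr = ssr[i])
  }
  best
}

# measured R1 at an arbitrary frequency, log-log interpolated
interp_r1 <- function(profile, at) {
  exp(approx(log(profile$frequencies), log(profile$r1_values),
             xout = log(at))$y)
}

# small, fast simulation configuration for I/O and CLI tests
tiny_config <- function(...) {
  sim_config(n_patients = 2, n_freq = 10, n_echoes = 100,
             recovery_points = 10, seed = 7, ...)
}
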