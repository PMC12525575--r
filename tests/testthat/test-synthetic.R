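test_that("cohort parameter sampling is deterministic and within the study ranges", {
  cfg <- sim_config(seed = 9)
  gt <- sample_cohort_params(cfg)
  expect_equal(nrow(gt), 18)  # 9 patients, tumor + reference each
  expect_equal(sample_cohort_params(cfg), gt)  # same seed, same cohort

  expect_true(all(gt$alpha >= 0.27 & gt$alpha <= 0.33))
  expect_true(all(gt$r2_fast / gt$r2_slow >= 1.9 &
                    gt$r2_fast / gt$r2_slow <= 4.9))
  expect_true(all(gt$a_fast < gt$a_slow))  # amplitude ratio below 1

  # paired reference exceeds its tumor by the configured dispersion factor
  for (p in unique(gt$patient)) {
    pair <- gt[gt$patient == p, ]
    expect_equal(pair$r1_at_ref[pair$group == "reference"],
                 1.15 * pair$r1_at_ref[pair$group == "tumor"])
  }

  solo <- sample_cohort_params(sim_config(n_patients = 4, paired = FALSE,
                                          seed = 9))
  expect_equal(nrow(solo), 4)
  expect_true(all(solo$group == "tumor"))

  expect_error(sim_config(rate_ratio_range = c(0.5, 2)),
               class = "relax_config_error")
  expect_error(sim_config(amp_ratio_range = c(0.2, 1.2)),
               class = "relax_config_error")
  expect_error(sim_config(alpha_range = c(0.4, 0.2)),
               class = "relax_config_error")
})

test_that("quadrupole peak term is a Lorentzian sum in the 2-4 MHz band", {
  nu <- log_grid(n = 50)
  expect_equal(qre_peak_term(nu, NULL), rep(0, 50))
  expect_equal(qre_peak_term(nu, data.frame(center = numeric(),
                                            width = numeric(),
                                            height = numeric())),
               rep(0, 50))

  single <- data.frame(center = 2.8e6, width = 1.5e5, height = 0.4)
  expect_equal(qre_peak_term(2.8e6, single), 0.4)  # maximum at the center
  expect_lt(qre_peak_term(2.8e6 + 1.5e5, single), 0.4)

  gt <- list(alpha = 0.3, r1_at_ref = 4)
  peaks <- relaxometry:::default_qre_peaks(gt, 0.08)
  expect_true(all(peaks$center >= 2e6 & peaks$center <= 4e6))
  expect_true(all(peaks$height <= 0.1 * 4 * (peaks$center / 1e6)^(-0.3)))

  expect_error(qre_peak_term(nu, data.frame(center = 2e6, width = -1,
                                            height = 0.1)),
               class = "relax_config_error")
})

test_that("generated dispersion profiles behave as configured", {
  cfg <- sim_config(seed = 3)
  gt <- sample_cohort_params(cfg)[1, ]

  clean <- generate_dispersion(gt, sim_config(seed = 3, profile_noise = 0))
  expect_true(18.7e6 %in% clean$frequencies)
  fit <- fit_dispersion_power_law(clean)
  expect_equal(fit$alpha, gt$alpha, tolerance = 1e-10)
  expect_equal(fit$r1_at_ref, gt$r1_at_ref, tolerance = 1e-10)

  # with QRE peaks, masking the 2-4 MHz band keeps alpha accurate
  qcfg <- sim_config(seed = 3, qre = TRUE)
  qprof <- generate_dispersion(gt, qcfg)
  masked <- fit_dispersion_power_law(qprof, exclude_band = c(2e6, 4e6))
  expect_lt(abs(masked$alpha - gt$alpha), 0.02)

  # noise calibration: empirical relative residual SD tracks the setting
  ncfg <- sim_config(seed = 3, n_freq = 150)
  nprof <- generate_dispersion(gt, ncfg)
  truth <- gt$r1_at_ref * (nprof$frequencies / 1e6)^(-gt$alpha)
  rel_sd <- sd(nprof$r1_values / truth - 1)
  expect_lt(abs(rel_sd - 0.03) / 0.03, 0.20)
})

test_that("full-pipeline mode emits recovery curves whose fits estimate R1", {
  cfg <- sim_config(seed = 4, n_freq = 6, recovery_noise = 0.005)
  gt <- sample_cohort_params(cfg)[1, ]
  out <- generate_dispersion(gt, cfg, with_curves = TRUE)
  expect_length(out$curves, length(out$profile$frequencies))
  r1_true <- gt$r1_at_ref * (out$profile$frequencies[3] / 1e6)^(-gt$alpha)
  est <- fit_recovery_monoexp(out$curves[[3]])
  expect_lt(abs(est$rate / r1_true - 1), 0.1)
})

test_that("generated CPMG decays recover ground truth", {
  cfg <- sim_config(seed = 8)
  gt <- sample_cohort_params(cfg)[2, ]

  dec <- generate_cpmg_decay(gt, cfg)
  expect_length(dec$times, 1000)

  clean <- generate_cpmg_decay(gt, sim_config(seed = 8, decay_noise = 0))
  fit <- fit_decay_biexp(clean)
  expect_equal(fit$r2_slow, gt$r2_slow, tolerance = 1e-6)
  expect_equal(fit$r2_fast, gt$r2_fast, tolerance = 1e-6)
  expect_equal(fit$a_slow, gt$a_slow, tolerance = 1e-6)

  nfit <- fit_decay_biexp(dec)
  truth_ratio <- gt$r2_fast / gt$r2_slow
  expect_lt(abs(nfit$r2_fast / nfit$r2_slow / truth_ratio - 1), 0.10)
})

test_that("cohorts are reproducible and physical", {
  cfg <- sim_config(seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(a$ground_truth, b$ground_truth)
  expect_equal(a$profiles, b$profiles)
  expect_equal(a$decays, b$decays)

  gt <- a$ground_truth
  r1_hf <- gt$r1_at_ref * (cfg$hf_frequency / 1e6)^(-gt$alpha)
  expect_true(all(gt$r2_slow >= r1_hf))
  expect_true(all(gt$r2_fast > gt$r2_slow))
})

test_that("noise-free cohort markers equal the ground-truth marker table", {
  cfg <- sim_config(seed = 21, profile_noise = 0, decay_noise = 0,
                    n_patients = 3)
  coh <- generate_cohort(cfg)
  gt <- coh$ground_truth

  fitted_rows <- lapply(seq_len(nrow(gt)), function(i) {
    id <- gt$sample_id[i]
    marker_set(id, gt$group[i],
               fit_dispersion_power_law(coh$profiles[[id]]),
               fit_decay_biexp(coh$decays[[id]]),
               profile = coh$profiles[[id]])
  })
  truth_rows <- lapply(seq_len(nrow(gt)), function(i) {
    marker_set(gt$sample_id[i], gt$group[i],
               power_law_fit(gt$alpha[i], gt$r1_at_ref[i]),
               bi_exp_fit(gt$r2_slow[i], gt$r2_fast[i],
                          gt$a_slow[i], gt$a_fast[i]),
               profile = coh$profiles[[gt$sample_id[i]]])
  })
  fitted_tab <- relaxometry:::round_marker_table(
    build_marker_table(do.call(rbind, fitted_rows)))
  truth_tab <- relaxometry:::round_marker_table(
    build_marker_table(do.call(rbind, truth_rows)))
  expect_equal(fitted_tab, truth_tab)
})
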