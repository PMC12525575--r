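test_that("model-mode xi is the closed form in alpha and the frequency ratio", {
  expect_equal(compute_xi(power_law_fit(0, 5)), 0)
  expect_equal(compute_xi(power_law_fit(1, 5)), 90)  # 100 (1 - 10^-1)
  for (a in c(0.1, 0.27, 0.30, 0.33, 0.8)) {
    expect_equal(compute_xi(power_law_fit(a, 7)), 100 * (1 - 10^(-a)))
    # depends only on the ratio nu2/nu1, not on their absolute values
    expect_equal(compute_xi(power_law_fit(a, 7), nu1 = 3e5, nu2 = 3e6),
                 compute_xi(power_law_fit(a, 7)))
  }
})

test_that("data-mode xi interpolates measured points log-log", {
  prof <- exact_profile(0.30, 20)
  # log-log interpolation is exact on an exact power law
  expect_equal(compute_xi(prof), 100 * (1 - 10^(-0.30)), tolerance = 1e-10)
  expect_error(compute_xi(prof, nu1 = 1e3, nu2 = 1e5),
               class = "relax_input_error")
  expect_error(compute_xi(prof, nu1 = 1e5, nu2 = 1e4),
               class = "relax_input_error")
})

test_that("rate and amplitude ratios match the published arithmetic", {
  p1r <- bi_exp_fit(10.8, 24.1, 0.7, 0.3)
  expect_equal(round(compute_rate_ratio(p1r), 1), 2.2)
  p7t <- bi_exp_fit(5.91, 28.8, 0.8, 0.2)
  expect_equal(round(compute_rate_ratio(p7t), 1), 4.9)
  eq <- bi_exp_fit(5, 5, 0.5, 0.5)
  expect_equal(compute_rate_ratio(eq), 1.0)

  expect_equal(compute_amp_ratio(bi_exp_fit(5, 15, 0.7, 0)), 0)
  expect_equal(compute_amp_ratio(bi_exp_fit(5, 15, 0.5, 0.5)), 100)
  expect_equal(compute_amp_ratio(bi_exp_fit(5, 15, 0.7, 0.3)), 100 * 3 / 7)
})

test_that("R2,slow/R1 flags unphysical values without rejecting them", {
  fit <- bi_exp_fit(10.8, 24.1, 0.7, 0.3)
  r <- compute_r2slow_over_r1(fit, r1 = 10.8 / 6.4)
  expect_equal(as.numeric(r), 6.4)
  expect_true(attr(r, "physical"))

  r1eq <- expect_silent(compute_r2slow_over_r1(fit, r1 = 10.8))
  expect_equal(as.numeric(r1eq), 1.0)

  expect_warning(bad <- compute_r2slow_over_r1(fit, r1 = 20), "unphysical")
  expect_false(attr(bad, "physical"))
})

test_that("ratio profiles divide pointwise with log-log regridding", {
  ref <- exact_profile(0.30, 23, id = "ref")
  tum <- exact_profile(0.30, 20, id = "tum")
  same <- ratio_profile(ref, ref)
  expect_equal(same$ratio, rep(1, nrow(same)))

  scaled <- dispersion_profile("t2", tum$frequencies, tum$r1_values / 1.15)
  expect_equal(ratio_profile(tum, scaled)$ratio, rep(1.15, 25))

  # matched alpha, pre-factors differing by k, on different grids
  tum2 <- exact_profile(0.30, 20, n = 31, id = "t3")
  rp <- ratio_profile(ref, tum2)
  expect_equal(rp$ratio, rep(23 / 20, nrow(rp)), tolerance = 1e-10)

  lowband <- dispersion_profile("lo", c(1e3, 2e3, 5e3), c(30, 25, 20))
  expect_error(ratio_profile(ref, lowband), class = "relax_input_error")
})

test_that("average_ratio averages pointwise with explicit exclusion", {
  ref <- exact_profile(0.30, 23, id = "r")
  grid <- ref$frequencies
  mk <- function(value) {
    out <- data.frame(frequency = grid, ratio = rep(value, length(grid)))
    class(out) <- c("ratio_series", "data.frame")
    out
  }
  one <- average_ratio(list(P1 = mk(1.3)))
  expect_equal(one$mean_series$ratio, mk(1.3)$ratio)
  expect_equal(one$grand_mean, 1.3)

  two <- average_ratio(list(P1 = mk(1.1), P2 = mk(1.2)))
  expect_equal(two$grand_mean, 1.15)

  # invariant to case ordering
  swapped <- average_ratio(list(P2 = mk(1.2), P1 = mk(1.1)))
  expect_equal(swapped$mean_series$ratio, two$mean_series$ratio)

  excl <- average_ratio(list(P1 = mk(1.1), P7 = mk(3)), exclude = "P7")
  expect_equal(excl$grand_mean, 1.1)
  expect_equal(excl$n, 1)
  expect_error(average_ratio(list(P1 = mk(1.1)), exclude = "P1"),
               class = "relax_input_error")
})

test_that("matched-alpha pairs with pre-factor ratio 1.15 average to 1.15", {
  # pairs share alpha so the true pointwise ratio is the constant pre-factor
  # ratio; 3 % profile noise then scatters the estimate around it
  cfg <- sim_config(seed = 5)
  ratios <- withr::with_seed(5, lapply(seq_len(9), function(p) {
    alpha <- runif(1, 0.27, 0.33)
    r1_t <- runif(1, 3, 5)
    gt_t <- list(sample_id = "t", alpha = alpha, r1_at_ref = r1_t,
                 seed = 100 + p)
    gt_r <- list(sample_id = "r", alpha = alpha,
                 r1_at_ref = 1.15 * r1_t, seed = 200 + p)
    ratio_profile(generate_dispersion(gt_r, cfg),
                  generate_dispersion(gt_t, cfg))
  }))
  names(ratios) <- paste0("P", seq_len(9))
  avg <- average_ratio(ratios)
  expect_lt(abs(avg$grand_mean - 1.15), 0.01)
  expect_equal(avg$n, 9)
})

test_that("group summaries use the population standard deviation", {
  markers <- data.frame(
    sample_id = c("a", "b", "c"), group = c("tumor", "tumor", "reference"),
    alpha = c(0.30, 0.32, 0.29), xi = c(50, 54, 48),
    r2_slow = c(6, 7, 8), r2_fast = c(18, 21, 16),
    amp_ratio = c(40, 50, 45), rate_ratio = c(3, 3, 2),
    r2slow_over_r1 = c(4, 5, 4), r1_at_18_7 = c(1.5, 1.4, 2))
  s <- summarize_group(markers, "tumor")
  expect_equal(attr(s, "n"), 2)
  expect_equal(s$mean[s$marker == "alpha"], 0.31)
  expect_equal(s$sd[s$marker == "alpha"], 0.01)  # population, not sample, SD

  single <- summarize_group(markers, "reference")
  expect_equal(single$mean[single$marker == "r2_slow"], 8)
  expect_equal(single$sd, rep(0, nrow(single)))

  # means lie between the group min and max for every marker
  for (m in s$marker) {
    v <- markers[markers$group == "tumor", m]
    expect_gte(s$mean[s$marker == m], min(v))
    expect_lte(s$mean[s$marker == m], max(v))
  }
  expect_error(summarize_group(markers, "margin"),
               class = "relax_input_error")
})

test_that("marker tables keep every sample and append group-average rows", {
  empty <- build_marker_table(data.frame())
  expect_s3_class(empty, "marker_table")
  expect_equal(nrow(empty), 0)
  expect_true(all(c("sample_id", "alpha", "rate_ratio") %in% names(empty)))

  pl <- power_law_fit(0.30, 20, alpha_stderr = 0.01, r_squared = 0.995)
  bi <- bi_exp_fit(6.3, 18.2, 0.7, 0.3, r_squared = 0.999)
  rows <- rbind(marker_set("P1 (t)", "tumor", pl, bi),
                marker_set("P1 (r)", "reference", pl, bi))
  tab <- build_marker_table(rows)
  expect_equal(nrow(tab), 4)  # 2 samples + 2 average rows
  expect_setequal(tab$sample_id[3:4], c("Avg. (t)", "Avg. (r)"))
  expect_false(any(tab$incomplete))

  rows2 <- rows
  rows2$alpha[1] <- NA
  tab2 <- build_marker_table(rows2)
  expect_true(tab2$incomplete[tab2$sample_id == "P1 (t)"])
  expect_equal(sum(tab2$sample_id == "P1 (t)"), 1)  # flagged, not dropped
})
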