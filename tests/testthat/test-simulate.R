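test_that("scan cadence follows the duty cycle", {
  expect_identical(length(scan_schedule(acquisition_config("MS1_only"), 10)), 40L)
  # DDA top-5: 0.25 + 5 x 0.15 = 1.0 s cycle
  expect_identical(length(scan_schedule(acquisition_config("DDA"), 10)), 10L)
  expect_error(scan_schedule(acquisition_config("DDA"), 0.5), "duty cycle")
})

test_that("scans-per-peak closed form matches counting the schedule", {
  withr::with_seed(31, {
    for (i in 1:50) {
      cfg <- acquisition_config(sample(c("MS1_only", "DDA"), 1),
                                ms1_scan_s = runif(1, 0.1, 0.6),
                                ms2_scan_s = runif(1, 0.05, 0.3))
      run_len <- runif(1, 5, 60)
      ctr <- runif(1, 1, run_len - 1); sg <- runif(1, 0.3, 5)
      counted <- sum(abs(scan_schedule(cfg, run_len) - ctr) <= 2 * sg)
      expect_identical(scans_per_peak(cfg, ctr, sg, run_len), as.integer(counted))
    }
  })
})

test_that("narrow peaks under a slow DDA cycle trigger the design warning", {
  cfg <- acquisition_config("DDA", iit_threshold_ppm = 100, seed = 1)
  sp <- sim_species("x", elution_center_s = 5, elution_sigma_s = 1.5,
                    apex_flux = 1e5)
  expect_identical(scans_per_peak(cfg, 5, 1.5, 10), 7L) # 6 s base < 8 scans
  expect_warning(simulate_acquisition(sp, cfg, 10), "Fewer than 8 MS1 scans")
  # wide peak: no warning
  cfg2 <- acquisition_config("MS1_only", seed = 1)
  expect_no_warning(simulate_acquisition(
    sim_species("x", elution_center_s = 15, elution_sigma_s = 2.5), cfg2, 30))
})

test_that("reported intensity is an unbiased flux estimate without gating", {
  cfg <- acquisition_config("MS1_only", iit_threshold_ppm = 100, seed = 12)
  sp <- dplyr::bind_rows(
    sim_species("minor", apex_flux = 2e4),
    sim_species("major", apex_flux = 4e6))
  scans <- simulate_acquisition(sp, cfg, 30)
  apex <- scans[abs(scans$time_s - 15) < 0.2, ]
  expect_equal(apex$intensity[apex$id == "major"], 4e6, tolerance = 0.01)
  expect_equal(apex$intensity[apex$id == "minor"], 2e4, tolerance = 0.1)
  expect_true(all(!scans$gated))
})

test_that("gating doubles the dominant species and spares the minor one", {
  base <- list(mode = "DDA", iit_threshold_ppm = 0.75, seed = 9)
  cfg_g <- do.call(acquisition_config, c(base, dominant_gain = 2))
  cfg_u <- do.call(acquisition_config, c(base, dominant_gain = 1))
  sp <- dplyr::bind_rows(
    sim_species("minor", apex_flux = 2e4),
    sim_species("major", apex_flux = 4e6))
  s_g <- simulate_acquisition(sp, cfg_g, 30)
  s_u <- simulate_acquisition(sp, cfg_u, 30)
  gated_times <- unique(s_g$time_s[s_g$gated])
  expect_true(length(gated_times) > 5)
  ratio_major <- sum(s_g$intensity[s_g$id == "major" & s_g$time_s %in% gated_times]) /
    sum(s_u$intensity[s_u$id == "major" & s_u$time_s %in% gated_times])
  ratio_minor <- sum(s_g$intensity[s_g$id == "minor" & s_g$time_s %in% gated_times]) /
    sum(s_u$intensity[s_u$id == "minor" & s_u$time_s %in% gated_times])
  expect_equal(ratio_major, 2, tolerance = 0.02)
  expect_equal(ratio_minor, 1, tolerance = 0.2)
  # zero-flux species reports zero everywhere
  sp0 <- dplyr::bind_rows(sp, sim_species("blank", apex_flux = 0))
  s0 <- simulate_acquisition(sp0, cfg_g, 30)
  expect_true(all(s0$intensity[s0$id == "blank"] == 0))
})

test_that("identical species quantify at 50% and XIC needs enough scans", {
  cfg <- acquisition_config("MS1_only", iit_threshold_ppm = 100, seed = 3)
  sp <- dplyr::bind_rows(
    sim_species("a", apex_flux = 2e6), sim_species("b", apex_flux = 2e6))
  scans <- simulate_acquisition(sp, cfg, 30)
  expect_equal(round(xic_and_quant(scans, "a", "b"), 1), 50.0)
  expect_error(xic_and_quant(scans, "a", "nope"), "not present")
  few <- scans[scans$time_s < 0.6, ]
  expect_error(xic_and_quant(few, "a", "b"), "Fewer than 3")
})

test_that("spike recovery is unbiased across seeds with gating off", {
  ests <- vapply(1:25, function(s) {
    spike_recovery(0.5, acquisition_config("MS1_only", iit_threshold_ppm = 100,
                                           seed = s))$rel_quant_pct
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.5), 2 * se + 0.01)
  # same seed, same answer
  a <- spike_recovery(0.2, acquisition_config("MS1_only", iit_threshold_ppm = 100,
                                              seed = 77))
  b <- spike_recovery(0.2, acquisition_config("MS1_only", iit_threshold_ppm = 100,
                                              seed = 77))
  expect_identical(a$rel_quant_pct, b$rel_quant_pct)
})

test_that("lower spike levels are recovered without bias too", {
  for (lvl in c(0.1, 0.2)) {
    ests <- vapply(1:15, function(s) {
      spike_recovery(lvl, acquisition_config("MS1_only", iit_threshold_ppm = 100,
                                             seed = 1000 + s))$rel_quant_pct
    }, numeric(1))
    se <- stats::sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - lvl), 2 * se + 0.005)
  }
})
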