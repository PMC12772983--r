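test_that("simulation is deterministic given the seed", {
  cfg <- signal_sim_config(duration_s = 300, fs = 50, seed = 7)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$samples, r2$samples)

  cc <- cohort_sim_config(n_women_sg = 3, n_women_mg = 3, n_tnl = 1,
                          n_apl = 1,
                          base = signal_sim_config(duration_s = 150, fs = 50),
                          seed = 9)
  s1 <- simulate_cohort(cc)
  s2 <- simulate_cohort(cc)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$recordings[[4]]$samples, s2$recordings[[4]]$samples)

  a1 <- inject_artifacts(r1, fraction = 0.2, seed = 3)
  a2 <- inject_artifacts(r1, fraction = 0.2, seed = 3)
  expect_identical(a1$recording$samples, a2$recording$samples)
  expect_identical(as.data.frame(a1$annotations), as.data.frame(a2$annotations))
})

test_that("burst-free configuration gives pure noise with the requested SD", {
  cfg <- signal_sim_config(duration_s = 1800, fs = 20, burst_rate = 0,
                           baseline_drift_amplitude = 0, noise_sd = 1,
                           seed = 11)
  rec <- simulate_recording(cfg)
  expect_equal(length(rec$samples), 36000)
  expect_lt(abs(sd(rec$samples) - 1), 0.05)
})

test_that("doubling burst amplitude doubles the noise-free peak-to-peak", {
  base <- signal_sim_config(duration_s = 600, fs = 50, noise_sd = 0,
                            baseline_drift_amplitude = 0,
                            burst_amplitude = 1, seed = 21)
  dbl <- base
  dbl$burst_amplitude <- 2
  p1 <- peak_to_peak(simulate_recording(base)$samples)
  p2 <- peak_to_peak(simulate_recording(dbl)$samples)
  expect_gt(p1, 0)
  expect_lt(abs(p2 / p1 - 2), 0.02)
})

test_that("cohort bookkeeping matches the configuration", {
  cc <- cohort_sim_config(n_women_sg = 10, n_women_mg = 4, n_tnl = 0,
                          n_apl = 0, recordings_per_woman = c(2, 2),
                          ga_range_routine = c(26, 36.9),
                          base = signal_sim_config(duration_s = 10, fs = 50),
                          seed = 2)
  sim <- simulate_cohort(cc)
  expect_equal(sum(sim$cohort$gestation_type == "SG"), 20)
  expect_equal(sum(sim$cohort$gestation_type == "MG"), 8)
  expect_true(all(!is.na(sim$cohort$woman_id)))
  expect_true(all(sim$cohort$ga_wog >= 26 & sim$cohort$ga_wog < 37))
  expect_false(any(duplicated(sim$cohort$recording_id)))
  expect_error(cohort_sim_config(n_women_sg = 0), "at least one woman")
})

test_that("programmed monotone amplitude trend maps to monotone PPA", {
  # shared signal seed isolates the programmed amplitude map from burst
  # realisation noise; noise and drift off per the trend-faithfulness
  # contract
  gas <- seq(26, 36, by = 1)
  ppa <- vapply(gas, function(ga) {
    cfg <- signal_sim_config(duration_s = 600, fs = 50, noise_sd = 0,
                             baseline_drift_amplitude = 0,
                             burst_amplitude = 0.4 + 0.09 * (ga - 26),
                             seed = 5)
    win <- preprocess_recording(simulate_recording(cfg, ga_wog = ga))
    median(window_features(win)$ppa)
  }, numeric(1))
  expect_true(all(diff(ppa) > 0))
  expect_equal(spearman_ga_correlation(ppa, gas)$rho, 1.0)
})

test_that("artifact injection honours the coverage contract", {
  cfg <- signal_sim_config(duration_s = 1800, fs = 20, seed = 13)
  rec <- simulate_recording(cfg)
  none <- inject_artifacts(rec, fraction = 0, seed = 1)
  expect_identical(none$recording$samples, rec$samples)
  expect_equal(nrow(none$annotations), 0)

  inj <- inject_artifacts(rec, fraction = 0.206, seed = 1)
  expect_gte(sum(inj$annotations$end_s - inj$annotations$start_s), 370.8)
  expect_error(inject_artifacts(rec, fraction = 1), "fraction")
})

test_that("annotated artifact intervals are excluded, not absorbed into features", {
  cfg <- signal_sim_config(duration_s = 1800, fs = 50, seed = 17,
                           burst_rate = 1)
  rec <- simulate_recording(cfg, ga_wog = 30, gestation_type = "SG")
  clean <- extract_recording_summary(rec)
  inj <- inject_artifacts(rec, fraction = 0.2, seed = 4)
  dirty <- extract_recording_summary(inj$recording, inj$annotations)
  for (f in c("median_ppa", "median_khe", "median_mdf", "median_sampen")) {
    expect_lt(abs(dirty[[f]] / clean[[f]] - 1), 0.05)
  }
})

test_that("burst power is concentrated in the two fast-wave bands", {
  for (seed in c(2, 5)) {
    cfg <- signal_sim_config(noise_sd = 0, baseline_drift_amplitude = 0,
                             seed = seed)
    rec <- simulate_recording(cfg)
    s <- welch_psd(rec$samples, rec$fs, nperseg = 2^15)
    inband <- (s$freq >= cfg$fwl_band[1] & s$freq <= cfg$fwl_band[2]) |
              (s$freq >= cfg$fwh_band[1] & s$freq <= cfg$fwh_band[2])
    expect_gte(sum(s$psd[inband]) / sum(s$psd), 0.95)
  }
})

test_that("higher regularity lowers mean window sample entropy", {
  sampen_windows <- function(reg) {
    out <- numeric()
    for (seed in 1:3) {
      cfg <- signal_sim_config(duration_s = 1200, fs = 50, regularity = reg,
                               burst_amplitude = 1.2, noise_sd = 0.15,
                               burst_rate = 1, seed = seed)
      win <- preprocess_recording(simulate_recording(cfg))
      out <- c(out, window_features(win)$sampen)
    }
    out
  }
  lo <- sampen_windows(0.2)
  hi <- sampen_windows(0.9)
  expect_gte(length(lo), 50)
  expect_gt(mean(lo, na.rm = TRUE), mean(hi, na.rm = TRUE))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(signal_sim_config(fwl_band = c(0.3, 0.2)), "band edges")
  expect_error(signal_sim_config(fwh_fraction = 1.4), "fwh_fraction")
  expect_error(signal_sim_config(regularity = -0.1), "regularity")
  expect_error(signal_sim_config(fs = 6), "twice the upper")
  expect_error(signal_sim_config(noise_sd = -1), "non-negative")
})
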