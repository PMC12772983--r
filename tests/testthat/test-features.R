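fwh_filter <- function(x, fs) {
  # re-create the fast-wave-high limited window via the public filter
  r <- bandpass_filter(ehg_recording(x, fs), 0.34, 4.0)
  r$samples
}

test_that("peak-to-peak amplitude follows its definition", {
  t <- seq(0, 120 - 0.05, by = 0.05)
  expect_equal(peak_to_peak(sin(2 * pi * 0.5 * t)), 2.0)
  expect_equal(peak_to_peak(rep(3.2, 100)), 0.0)
  expect_equal(peak_to_peak(c(-3, 0, 5)), 8.0)
  expect_error(peak_to_peak(numeric()), "empty")
  # linear scaling
  set.seed(1)
  x <- rnorm(500)
  expect_equal(peak_to_peak(2.5 * x), 2.5 * peak_to_peak(x))
})

test_that("envelope kurtosis is scale-invariant and ranks burstiness", {
  set.seed(4)
  x <- fwh_filter(rnorm(2400), 20)
  expect_equal(hilbert_envelope_kurtosis(7.3 * x, 20),
               hilbert_envelope_kurtosis(x, 20), tolerance = 1e-12)

  t <- seq(0, 120 - 0.05, by = 0.05)
  burst <- numeric(2400)
  burst[1100:1300] <- sin(2 * pi * 1 * t[1100:1300])
  continuous <- sin(2 * pi * 1 * t) * sqrt(mean(burst^2) / 0.5)
  expect_gt(hilbert_envelope_kurtosis(burst + 1e-6 * rnorm(2400), 20),
            hilbert_envelope_kurtosis(continuous + 1e-6 * rnorm(2400), 20))

  expect_true(is.na(hilbert_envelope_kurtosis(rep(1, 2400), 20)))
})

test_that("median frequency matches analytic line spectra", {
  t <- seq(0, 120 - 0.05, by = 0.05)
  bin <- 20 / 1200  # Welch segment resolution

  expect_equal(median_frequency(sin(2 * pi * 0.5 * t), 20), 0.5,
               tolerance = bin)
  two <- sin(2 * pi * 0.3 * t + 1.1) + sin(2 * pi * 0.7 * t + 0.3)
  expect_equal(median_frequency(two, 20), 0.5, tolerance = 0.05)
  oob <- sin(2 * pi * 0.1 * t) + sin(2 * pi * 0.5 * t)
  expect_equal(median_frequency(oob, 20), 0.5, tolerance = bin)

  # monotonicity in the carrier of a narrowband burst
  env <- exp(-0.5 * ((t - 60) / 10)^2)
  m3 <- median_frequency(env * sin(2 * pi * 0.3 * t), 20)
  m7 <- median_frequency(env * sin(2 * pi * 0.7 * t), 20)
  expect_lt(m3, m7)
  expect_gt(m7 - m3, 0.3)

  expect_true(is.na(median_frequency(rep(0.7, 2400), 20)))
  expect_error(median_frequency(two, 20, band = c(1, 0.2)), "band edges")
})

test_that("sample entropy matches its definition on canonical inputs", {
  alt <- rep(c(1, -1), 50)
  expect_equal(sample_entropy(alt), 0.0)

  set.seed(8)
  x <- runif(600)
  expect_equal(sample_entropy(5 * x + 3), sample_entropy(x), tolerance = 1e-12)
  expect_equal(sample_entropy(-2 * x), sample_entropy(x), tolerance = 1e-12)

  expect_true(is.na(sample_entropy(rep(1, 100))))
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "at least")
})

test_that("optimized sample entropy equals the brute-force oracle", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(50:1200, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                cumsum(rnorm(n)),
                sin(seq_len(n) / 5) + rnorm(n, sd = 0.2))
    got <- sample_entropy(x)
    want <- sampen_oracle(x, 2, 0.2 * sd(x))
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("per-window features and medians aggregate as specified", {
  feats <- data.frame(start_s = c(0, 60, 120),
                      ppa = c(1, 2, 100), khe = c(3, NA, 5),
                      mdf = c(0.4, 0.5, 0.6), sampen = c(NA, NA, NA))
  s <- summarize_recording(feats, list(recording_id = "r1", woman_id = "w1",
                                       ga_wog = 30, gestation_type = "SG",
                                       stage_label = "routine"))
  expect_equal(s$median_ppa, 2)          # robust to the outlier window
  expect_equal(s$median_khe, 4)          # NA windows excluded per feature
  expect_true(is.na(s$median_sampen))    # all-undefined stays undefined
  expect_equal(s$n_windows, 3)

  # permutation invariance and the single-window case
  perm <- feats[c(3, 1, 2), ]
  expect_equal(summarize_recording(perm, list(recording_id = "r1"))$median_ppa,
               s$median_ppa)
  one <- summarize_recording(feats[2, ], list(recording_id = "r1"))
  expect_equal(one$median_ppa, 2)
  expect_true(is.na(one$median_khe))
  expect_error(summarize_recording(feats[0, ], list()), "excluded")
})

test_that("window_features computes all four features per window", {
  set.seed(2)
  rec <- ehg_recording(rnorm(20 * 400), fs = 20)
  win <- segment_windows(exclude_artifacts(bandpass_filter(rec)),
                         window_s = 120, overlap = 0.5)
  wf <- window_features(win)
  expect_equal(nrow(wf), nrow(win$samples))
  expect_true(all(wf$ppa > 0))
  expect_true(all(wf$mdf >= 0.2 & wf$mdf <= 1.0))
  expect_true(all(wf$sampen > 0))
  expect_true(all(is.finite(wf$khe)))
})
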