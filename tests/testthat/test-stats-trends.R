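test_that("stage stratification applies the 32/37 WoG thresholds", {
  cohort <- data.frame(
    recording_id = c("a", "b", "c", "d"),
    ga_wog = c(30.0, 32.0, 36.9, 40.5),
    stage_label = c("routine", "routine", "routine", "APL"),
    stringsAsFactors = FALSE)
  out <- stratify_by_stage(cohort)
  expect_equal(as.character(out$stage), c("Early3T", "Late3T", "Late3T", "APL"))

  bad <- cohort
  bad$ga_wog[1] <- 38
  expect_error(stratify_by_stage(bad), "without TNL/APL")
})

test_that("Spearman correlation matches monotone expectations and the oracle", {
  r <- spearman_ga_correlation(c(1, 4, 9), c(28, 30, 34))
  expect_equal(r$rho, 1.0)
  expect_equal(spearman_ga_correlation(c(9, 4, 1), c(28, 30, 34))$rho, -1.0)

  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 4)
  expect_equal(spearman_ga_correlation(y, x)$rho, spearman_oracle(y, x),
               tolerance = 1e-12)

  set.seed(6)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    a <- sample(0:9, n, replace = TRUE)    # heavy ties
    b <- rnorm(n) + 0.3 * a
    expect_equal(spearman_ga_correlation(a, b)$rho, spearman_oracle(a, b),
                 tolerance = 1e-12)
  }

  z <- spearman_ga_correlation(rep(1, 10), 1:10)
  expect_true(is.na(z$rho) && is.na(z$p_value))
  expect_error(spearman_ga_correlation(1:2, 1:2), "at least 3")
})

test_that("small-sample Spearman p-values come from exact permutation", {
  r <- spearman_ga_correlation(c(1, 4, 9), c(28, 30, 34))
  expect_equal(r$method, "exact permutation")
  expect_equal(r$p_value, 2 / 6)  # both perfect orderings out of 3!
  r2 <- spearman_ga_correlation(rnorm(20), rnorm(20))
  expect_equal(r2$method, "t approximation")
})

test_that("Wilcoxon comparison reproduces exact references", {
  same <- wilcoxon_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1.0)
  expect_false(same$significant)

  r <- wilcoxon_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, wilcox_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  expect_error(wilcoxon_compare(numeric(), 1:3), "empty")
  expect_warning(wilcoxon_compare(c(1, 2), c(3, 4, 5)), "fewer than 3")
})

test_that("GAM trends recover known mean structures", {
  ga <- seq(26, 40, length.out = 60)
  lin <- fit_gam_trend(2 * ga, ga)
  interior <- lin$grid$ga > 27 & lin$grid$ga < 39
  expect_lt(max(abs(lin$grid$fit - 2 * lin$grid$ga)[interior]), 1e-3)
  expect_true(all(lin$grid$lower <= lin$grid$fit + 1e-12 &
                  lin$grid$fit <= lin$grid$upper + 1e-12))

  const_large <- fit_gam_trend(rep(5, 300), seq(26, 40, length.out = 300))
  expect_equal(const_large$grid$fit, rep(5, nrow(const_large$grid)),
               tolerance = 1e-8)
  expect_lt(mean(const_large$grid$upper - const_large$grid$lower), 1e-6)
  # with noise around a constant mean, the band tightens as n grows
  set.seed(44)
  noisy_small <- fit_gam_trend(5 + rnorm(30, sd = 0.5),
                               seq(26, 40, length.out = 30))
  noisy_large <- fit_gam_trend(5 + rnorm(480, sd = 0.5),
                               seq(26, 40, length.out = 480))
  expect_lt(mean(noisy_large$grid$upper - noisy_large$grid$lower),
            mean(noisy_small$grid$upper - noisy_small$grid$lower))

  set.seed(12)
  ga <- runif(200, 26, 41)
  y <- sin(ga / 2) + rnorm(200, sd = 0.3)
  fit <- fit_gam_trend(y, ga)
  interior <- fit$grid$ga > 27 & fit$grid$ga < 40
  rmse <- sqrt(mean((fit$grid$fit - sin(fit$grid$ga / 2))[interior]^2))
  expect_lt(rmse, 0.3)

  expect_error(fit_gam_trend(rnorm(12), rep(c(26, 27, 28), 4)),
               "reduce `k`")
})

test_that("full analysis runs, degrades gracefully, and flags sensibly", {
  cohort <- make_meta_cohort(n_sg = 50, n_mg = 50, seed = 2, sg_term = 12)
  an <- run_full_analysis(cohort, seed = 3)
  expect_s3_class(an, "ehg_analysis")
  expect_equal(nrow(an$correlations), 8)
  expect_true(all(c("ppa.SG", "sampen.MG") %in% names(an$trends)))
  expect_true(all(an$comparisons$significant == (an$comparisons$p_value < 0.05)))
  # programmed linear PPA rise is detected in both groups
  ppa <- an$correlations[an$correlations$feature == "ppa", ]
  expect_true(all(ppa$rho > 0 & ppa$p_value < 0.05))

  # SG-only cohort: MG results omitted and logged, no error
  sg_only <- cohort[cohort$gestation_type == "SG", ]
  an2 <- run_full_analysis(sg_only, seed = 3)
  expect_false(any(an2$correlations$group == "MG"))
  expect_true(any(grepl("MG", an2$log)) || any(grepl("skipped", an2$log)))
})

test_that("the full pipeline holds its type-I error under a null generator", {
  # scaled down for runtime: short recordings, small early-third-trimester
  # groups, 30 replicates; both gestation types share the SG trend so the
  # SG-vs-MG contrast is null in every replicate
  reps <- 30
  valid <- 0
  rejections <- 0
  for (rep in seq_len(reps)) {
    cc <- cohort_sim_config(
      n_women_sg = 10, n_women_mg = 10, n_tnl = 0, n_apl = 0,
      recordings_per_woman = c(2, 2), ga_range_routine = c(26, 32),
      base = signal_sim_config(duration_s = 360, fs = 50),
      trend_mg = default_trend_sg, seed = 1000 + rep)
    sim <- simulate_cohort(cc)
    cohort <- extract_cohort_features(sim$recordings)
    an <- run_full_analysis(cohort, seed = rep)
    cmp <- an$comparisons
    row <- cmp[cmp$feature == "ppa" &
               cmp$contrast == "SG-Early3T vs MG-Early3T", ]
    if (!is.null(row) && nrow(row) == 1) {
      valid <- valid + 1
      if (isTRUE(row$significant)) rejections <- rejections + 1
    }
  }
  expect_gte(valid, 25)
  # binomial(30, 0.05): P(X > 5) ~ 0.002
  expect_lte(rejections, 5)
})
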