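#' Configuration for one simulated EHG recording
#'
#' The signal model is: sparse contraction bursts (Gaussian-tapered
#' envelopes times a mixture of a fast-wave-low and a fast-wave-high
#' narrowband oscillation), plus slow baseline drift below 0.1 Hz, plus
#' broadband Gaussian measurement noise.  Amplitudes are arbitrary units —
#' surface EHG has no absolute calibration, and all downstream features are
#' unit-agnostic or scale linearly.
#'
#' `regularity` in `[0, 1]` controls the frequency jitter of the
#' fast-wave-high oscillator: 1 gives a nearly pure tone (low sample
#' entropy), 0 gives heavy jitter (high sample entropy).  It is a
#' monotone handle on signal regularity, not a physiological model.
#'
#' @param duration_s recording length in seconds (default 1800: the
#'   30-minute clinical protocol).
#' @param fs sampling rate in Hz (default 500, the acquisition rate).
#' @param burst_rate contraction bursts per minute.
#' @param burst_duration_s burst length in seconds.
#' @param burst_amplitude peak burst amplitude in signal units.
#' @param fwl_band,fwh_band fast-wave-low / fast-wave-high bands in Hz.
#' @param fwh_fraction share of burst power in the fast-wave-high band,
#'   in `[0, 1]`.
#' @param baseline_drift_amplitude amplitude of the sub-0.1 Hz drift.
#' @param noise_sd SD of the additive white noise.
#' @param regularity burst-waveform regularity in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return A list of class `signal_sim_config`.
#' @export
signal_sim_config <- function(duration_s = 1800, fs = 500, burst_rate = 0.6,
                              burst_duration_s = 35, burst_amplitude = 1,
                              fwl_band = c(0.13, 0.26),
                              fwh_band = c(0.34, 4.0), fwh_fraction = 0.6,
                              baseline_drift_amplitude = 0.5, noise_sd = 0.3,
                              regularity = 0.5, seed = 1L) {
  cfg <- list(duration_s = duration_s, fs = fs, burst_rate = burst_rate,
              burst_duration_s = burst_duration_s,
              burst_amplitude = burst_amplitude, fwl_band = fwl_band,
              fwh_band = fwh_band, fwh_fraction = fwh_fraction,
              baseline_drift_amplitude = baseline_drift_amplitude,
              noise_sd = noise_sd, regularity = regularity,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "signal_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$duration_s <= 0 || cfg$fs <= 0) stopf("duration and fs must be positive")
  for (b in list(cfg$fwl_band, cfg$fwh_band))
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      stopf("band edges must satisfy 0 < low < high")
  if (cfg$fs <= 2 * cfg$fwh_band[2])
    stopf("fs must exceed twice the upper fast-wave-high edge")
  if (cfg$fwh_fraction < 0 || cfg$fwh_fraction > 1)
    stopf("fwh_fraction must lie in [0, 1]")
  if (cfg$regularity < 0 || cfg$regularity > 1)
    stopf("regularity must lie in [0, 1]")
  amps <- c(cfg$burst_amplitude, cfg$baseline_drift_amplitude, cfg$noise_sd,
            cfg$burst_rate, cfg$burst_duration_s)
  if (any(amps < 0)) stopf("rates and amplitudes must be non-negative")
  invisible(cfg)
}

## AR(1) noise with ~`tau_s` correlation time, unit marginal variance.
ar1_noise <- function(n, fs, tau_s = 0.7) {
  a <- exp(-1 / (tau_s * fs))
  e <- rnorm(n, sd = sqrt(1 - a^2))
  as.numeric(stats::filter(e, a, method = "recursive"))
}

## One burst waveform of `len` samples at rate fs.
## Draw order is independent of all amplitude parameters so that scaling
## `burst_amplitude` with the same seed rescales the identical waveform.
burst_waveform <- function(len, fs, cfg) {
  f_l <- cfg$fwl_band[1] + diff(cfg$fwl_band) * runif(1, 0.4, 0.6)
  f_h <- cfg$fwh_band[1] + diff(cfg$fwh_band) * runif(1, 0.03, 0.15)
  ## log-normal instantaneous-frequency jitter: always positive, and wide
  ## enough at low regularity to turn the oscillation into a chirpy
  ## broadband process (high sample entropy) while staying inside the
  ## fast-wave-high band most of the time
  jit_h <- 1.2 * (1 - cfg$regularity)
  z_h <- ar1_noise(len, fs, tau_s = 0.4)
  z_l <- ar1_noise(len, fs, tau_s = 2)
  ph0 <- runif(2, 0, 2 * pi)
  phase_h <- 2 * pi * cumsum(f_h * exp(jit_h * z_h)) / fs
  phase_l <- 2 * pi * cumsum(f_l * (1 + 0.05 * z_l)) / fs
  tt <- seq_len(len) - (len + 1) / 2
  env <- exp(-0.5 * (tt / (len / 6))^2)
  env * (sqrt(1 - cfg$fwh_fraction) * sin(phase_l + ph0[1]) +
         sqrt(cfg$fwh_fraction) * sin(phase_h + ph0[2]))
}

#' Simulate one EHG recording
#'
#' Deterministic given the configuration seed.  Burst onsets follow a
#' Poisson process thinned so bursts never overlap; each burst is a
#' Gaussian-tapered sum of one fast-wave-low and one fast-wave-high
#' narrowband oscillation with powers split by `fwh_fraction`.
#'
#' @param config a [signal_sim_config()].
#' @param ga_wog gestational age metadata (weeks of gestation).
#' @param gestation_type `"SG"` or `"MG"`.
#' @param recording_id,woman_id,stage_label metadata carried on the result.
#' @return An [ehg_recording()] of `round(duration_s * fs)` samples.
#' @export
simulate_recording <- function(config, ga_wog = NA_real_,
                               gestation_type = NA_character_,
                               recording_id = "sim", woman_id = "simw",
                               stage_label = NA_character_) {
  validate_sim_config(config)
  n <- round(config$duration_s * config$fs)
  fs <- config$fs
  x <- with_seed(config$seed, {
    ## noise is band-limited to the union of the two fast-wave bands so
    ## that `noise_sd` is the in-band noise floor the features actually
    ## see after preprocessing (white noise at 500 Hz would be almost
    ## entirely removed by the 0.1-4 Hz filter)
    noise <- fft_bandpass(rnorm(n), fs, min(0.1, config$fwl_band[1]),
                          config$fwh_band[2])
    noise <- noise / max(1e-12, sd(noise))
    drift <- numeric(n)
    t <- (0:(n - 1)) / fs
    fd <- runif(3, 0.01, 0.08)
    pd <- runif(3, 0, 2 * pi)
    ad <- runif(3, 0.3, 1)
    for (k in 1:3) drift <- drift + ad[k] * sin(2 * pi * fd[k] * t + pd[k])
    drift <- drift / max(1e-12, max(abs(drift)))
    burst <- numeric(n)
    if (config$burst_rate > 0 && config$burst_duration_s > 0 &&
        config$duration_s > config$burst_duration_s) {
      lambda <- config$burst_rate / 60 * config$duration_s
      nb <- rpois(1, lambda)
      if (nb > 0) {
        onset <- sort(runif(nb, 0, config$duration_s - config$burst_duration_s))
        keep <- logical(nb)
        last_end <- -Inf
        for (i in seq_len(nb)) {
          if (onset[i] >= last_end) {
            keep[i] <- TRUE
            last_end <- onset[i] + config$burst_duration_s
          }
        }
        onset <- onset[keep]
        len <- round(config$burst_duration_s * fs)
        for (o in onset) {
          i0 <- round(o * fs) + 1
          i1 <- min(n, i0 + len - 1)
          burst[i0:i1] <- burst[i0:i1] + burst_waveform(len, fs, config)[1:(i1 - i0 + 1)]
        }
      }
    }
    config$burst_amplitude * burst +
      config$baseline_drift_amplitude * drift +
      config$noise_sd * noise
  })
  ehg_recording(x, fs = fs, recording_id = recording_id, woman_id = woman_id,
                ga_wog = ga_wog, gestation_type = gestation_type,
                stage_label = stage_label)
}

#' Overwrite random intervals with motion-artifact transients
#'
#' Emulates the motion artifacts that are visually rejected in clinical
#' practice: randomly placed, non-overlapping intervals are overwritten
#' with clipped high-amplitude ramps, and the matching half-open annotation
#' intervals are returned.  Artifact morphology is irrelevant downstream —
#' annotated intervals are excluded, never repaired — so only the coverage
#' contract matters: annotated intervals total at least
#' `fraction * duration` seconds.
#'
#' @param recording an [ehg_recording()].
#' @param fraction target fraction of the duration to corrupt, in `[0, 1)`
#'   (the clinical rejection rate is about 0.206).
#' @param seed integer RNG seed.
#' @return A list with `recording` (corrupted copy) and `annotations`
#'   (an [ehg_annotations()] object).
#' @export
inject_artifacts <- function(recording, fraction = 0.206, seed = 1L) {
  stopifnot(inherits(recording, "ehg_recording"))
  if (fraction < 0 || fraction >= 1) stopf("`fraction` must lie in [0, 1)")
  if (fraction == 0)
    return(list(recording = recording, annotations = ehg_annotations()))
  dur <- recording_duration(recording)
  fs <- recording$fs
  target <- fraction * dur
  res <- with_seed(seed, {
    s <- numeric(); e <- numeric()
    covered <- 0
    tries <- 0
    while (covered < target && tries < 10000) {
      tries <- tries + 1
      len <- runif(1, 5, 25)
      len <- min(len, dur)
      st <- runif(1, 0, dur - len)
      en <- st + len
      if (any(st < e + 1 & en > s - 1)) next
      s <- c(s, st); e <- c(e, en)
      covered <- covered + len
    }
    ## top up deterministically if rejection sampling stalled
    if (covered < target) {
      gap <- target - covered
      e[length(e)] <- min(dur, e[length(e)] + gap)
    }
    amp <- 8 * max(sd(recording$samples), 1e-12)
    rec <- recording
    for (i in seq_along(s)) {
      i0 <- floor(s[i] * fs) + 1
      i1 <- min(length(rec$samples), ceiling(e[i] * fs))
      idx <- i0:i1
      tt <- (idx - i0) / fs
      ramp <- amp * (2 * ((0.5 * tt) %% 1) - 1)
      rec$samples[idx] <- pmax(pmin(ramp, 0.8 * amp), -0.8 * amp)
    }
    list(recording = rec, annotations = ehg_annotations(s, e))
  })
  res
}

#' Configuration for a simulated cohort
#'
#' Describes a third-trimester study population: singleton (SG) and
#' multiple/twin (MG) women attending routine check-ups between 26 and 37
#' weeks of gestation, plus additional SG groups at term (TNL, around 39
#' WoG) and in the active phase of labour (APL, beyond 40 WoG), one
#' recording each.  Gestational-age trends enter through the two trend
#' functions mapping GA to signal-model parameters; the defaults encode
#' the qualitative electrophysiology: contraction amplitude (hence PPA and
#' envelope impulsiveness) rising with GA, regularity rising with GA
#' (sample entropy falling), and MG offsets — earlier uterine activation —
#' concentrated before 32 WoG and vanishing by 32 WoG.
#'
#' @param n_women_sg,n_women_mg number of routine-check-up women per group.
#' @param n_tnl,n_apl number of term-not-in-labour and active-phase-of-
#'   labour SG women (one recording each).
#' @param recordings_per_woman integer range `c(min, max)` of routine
#'   recordings per woman.
#' @param ga_range_routine GA range (weeks) for routine recordings.
#' @param ga_range_tnl,ga_range_apl GA ranges for the term groups.
#' @param woman_sd SD of the log-normal woman-level amplitude effect
#'   (0 disables it).
#' @param base a [signal_sim_config()] used as the template for every
#'   recording (its `burst_amplitude`, `regularity` and `seed` are
#'   overridden per recording).
#' @param trend_sg,trend_mg functions `ga -> named list` of
#'   [signal_sim_config()] overrides; see [default_trend_sg()].
#' @param seed integer master seed; the same seed reproduces the identical
#'   cohort.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_women_sg = 40, n_women_mg = 40, n_tnl = 17,
                              n_apl = 10, recordings_per_woman = c(1, 3),
                              ga_range_routine = c(26, 37),
                              ga_range_tnl = c(38.5, 39.5),
                              ga_range_apl = c(40, 41.5), woman_sd = 0.15,
                              base = signal_sim_config(),
                              trend_sg = default_trend_sg,
                              trend_mg = default_trend_mg, seed = 1L) {
  if (n_women_sg <= 0 || n_women_mg <= 0)
    stopf("both groups need at least one woman")
  if (length(recordings_per_woman) != 2 ||
      recordings_per_woman[1] < 1 ||
      recordings_per_woman[1] > recordings_per_woman[2])
    stopf("recordings_per_woman must be c(min, max) with 1 <= min <= max")
  structure(list(n_women_sg = n_women_sg, n_women_mg = n_women_mg,
                 n_tnl = n_tnl, n_apl = n_apl,
                 recordings_per_woman = recordings_per_woman,
                 ga_range_routine = ga_range_routine,
                 ga_range_tnl = ga_range_tnl, ga_range_apl = ga_range_apl,
                 woman_sd = woman_sd, base = base, trend_sg = trend_sg,
                 trend_mg = trend_mg, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Default gestational-age trend functions
#'
#' `default_trend_sg()` maps GA to signal-model overrides for singleton
#' pregnancies: burst amplitude grows linearly from 0.4 at 26 WoG by
#' 0.09 per week (starting near the noise floor, so envelope impulsiveness
#' rises with it), and regularity from 0.25 by 0.03 per week (capped at
#' 0.95), so peak-to-peak amplitude and envelope kurtosis rise while
#' sample entropy falls across the third trimester and into labour.
#' `default_trend_mg()` adds the multiple-gestation offsets: an extra
#' amplitude term `0.5 * (32 - ga) / 6` and regularity term
#' `0.25 * (32 - ga) / 6`, both positive only before 32 WoG — earlier
#' uterine activation that converges to the SG trajectory by 32 WoG.
#'
#' @param ga gestational age in weeks.
#' @return A named list of [signal_sim_config()] overrides.
#' @export
default_trend_sg <- function(ga) {
  list(burst_amplitude = 0.4 + 0.09 * (ga - 26),
       regularity = min(0.95, max(0, 0.25 + 0.03 * (ga - 26))))
}

#' @rdname default_trend_sg
#' @export
default_trend_mg <- function(ga) {
  sg <- default_trend_sg(ga)
  early <- max(0, 32 - ga) / 6
  list(burst_amplitude = sg$burst_amplitude + 0.5 * early,
       regularity = min(0.95, sg$regularity + 0.25 * early))
}

#' Simulate a whole EHG cohort
#'
#' Draws women, visit gestational ages and per-recording signal-model
#' parameters from the cohort configuration, simulates every recording,
#' and returns both the recordings and the cohort metadata table.
#' Deterministic given the configuration seed.
#'
#' @param config a [cohort_sim_config()].
#' @return A list with `recordings` (list of [ehg_recording()]) and
#'   `cohort` (data frame with `recording_id`, `woman_id`, `ga_wog`,
#'   `gestation_type`, `stage_label`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  plan <- with_seed(config$seed, {
    rows <- list()
    add_woman <- function(wid, type, stage, gas) {
      eff <- if (config$woman_sd > 0) exp(rnorm(1, 0, config$woman_sd)) else 1
      for (ga in gas)
        rows[[length(rows) + 1]] <<- data.frame(
          woman_id = wid, ga_wog = ga, gestation_type = type,
          stage_label = stage, woman_effect = eff)
    }
    nrec <- function() {
      ks <- config$recordings_per_woman[1]:config$recordings_per_woman[2]
      if (length(ks) == 1L) ks else sample(ks, 1)
    }
    for (w in seq_len(config$n_women_sg))
      add_woman(sprintf("SGW%03d", w), "SG", "routine",
                sort(runif(nrec(), config$ga_range_routine[1],
                           config$ga_range_routine[2])))
    for (w in seq_len(config$n_women_mg))
      add_woman(sprintf("MGW%03d", w), "MG", "routine",
                sort(runif(nrec(), config$ga_range_routine[1],
                           config$ga_range_routine[2])))
    for (w in seq_len(config$n_tnl))
      add_woman(sprintf("TNLW%03d", w), "SG", "TNL",
                runif(1, config$ga_range_tnl[1], config$ga_range_tnl[2]))
    for (w in seq_len(config$n_apl))
      add_woman(sprintf("APLW%03d", w), "SG", "APL",
                runif(1, config$ga_range_apl[1], config$ga_range_apl[2]))
    plan <- do.call(rbind, rows)
    plan$recording_id <- sprintf("R%04d", seq_len(nrow(plan)))
    plan$seed <- sample.int(.Machine$integer.max - 1L, nrow(plan))
    plan
  })
  recordings <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    ga <- plan$ga_wog[i]
    trend <- if (plan$gestation_type[i] == "SG") config$trend_sg(ga)
             else config$trend_mg(ga)
    cfg <- config$base
    for (nm in names(trend)) cfg[[nm]] <- trend[[nm]]
    cfg$burst_amplitude <- cfg$burst_amplitude * plan$woman_effect[i]
    cfg$seed <- plan$seed[i]
    recordings[[i]] <- simulate_recording(
      cfg, ga_wog = ga, gestation_type = plan$gestation_type[i],
      recording_id = plan$recording_id[i], woman_id = plan$woman_id[i],
      stage_label = plan$stage_label[i])
  }
  cohort <- plan[, c("recording_id", "woman_id", "ga_wog", "gestation_type",
                     "stage_label")]
  rownames(cohort) <- NULL
  list(recordings = recordings, cohort = cohort)
}
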