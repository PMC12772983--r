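#' Peak-to-peak amplitude of an analysis window
#'
#' `max(x) - min(x)`, a proxy for contraction intensity, computed on the
#' 0.1-4 Hz band-limited signal.  Scales linearly with the input.
#'
#' @param x numeric vector (one analysis window).
#' @return Peak-to-peak amplitude in signal units (non-negative).
#' @export
peak_to_peak <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) stopf("empty window")
  if (any(!is.finite(x))) return(NA_real_)
  max(x) - min(x)
}

#' Kurtosis of the Hilbert envelope
#'
#' Pearson (non-excess) kurtosis of the magnitude of the analytic signal: a
#' proxy for impulsiveness.  A stationary Gaussian signal has a Rayleigh
#' envelope with kurtosis 3.245; isolated high-amplitude bursts inflate the
#' fourth moment well beyond that.  The analytic signal is computed on the
#' full window without tapering and the first and last `edge_trim_s`
#' seconds of the envelope are discarded before the moments, because the
#' frequency-domain Hilbert transformer rings at window edges.
#' Scale-invariant: `KHE(a * x) = KHE(x)` for `a > 0`.
#'
#' @param x numeric vector (window, band-limited 0.1-4 Hz).
#' @param fs sampling rate in Hz.
#' @param edge_trim_s seconds of envelope discarded at each end.
#' @return Kurtosis (unitless); `NA` for a zero-variance envelope.
#' @export
hilbert_envelope_kurtosis <- function(x, fs, edge_trim_s = 2) {
  x <- as.numeric(x)
  if (length(x) == 0L) stopf("empty window")
  env <- Mod(analytic_signal(x))
  k <- round(edge_trim_s * fs)
  if (2 * k >= length(env) - 4) stopf("window too short for edge trimming")
  if (k > 0) env <- env[(k + 1):(length(env) - k)]
  mu <- mean(env)
  v <- mean((env - mu)^2)
  if (v <= .Machine$double.eps * mu^2) return(NA_real_)
  mean((env - mu)^4) / v^2
}

#' Median frequency of an analysis window
#'
#' Median of the in-band power spectral distribution: the frequency
#' splitting the PSD restricted to `band` (default 0.2-1 Hz, chosen to
#' avoid maternal cardiac interference) into equal halves.  The PSD is a
#' Welch estimate (Hann taper, 50% overlap, 60-s segments by default,
#' giving about 0.017 Hz resolution at 20 Hz).  The half-power crossing is
#' linearly interpolated within bins; when the cumulative spectrum sits on
#' a plateau at exactly half power (e.g. two equal tones), the midpoint of
#' the plateau is returned — the median-interval convention.
#'
#' @param x numeric vector (window).
#' @param fs sampling rate in Hz.
#' @param band frequency band in Hz over which the median is taken.
#' @param nperseg Welch segment length in samples.
#' @param estimator `"welch"` (default) or `"periodogram"` (single
#'   full-window Hann periodogram).
#' @return Median frequency in Hz, inside `band`; `NA` when the in-band
#'   power is zero.
#' @export
median_frequency <- function(x, fs, band = c(0.2, 1.0), nperseg = 1200,
                             estimator = c("welch", "periodogram")) {
  estimator <- match.arg(estimator)
  x <- as.numeric(x)
  if (length(x) == 0L) stopf("empty window")
  if (band[1] >= band[2]) stopf("band edges must satisfy low < high")
  s <- if (estimator == "welch") welch_psd(x, fs, nperseg = nperseg)
       else welch_psd(x, fs, nperseg = length(x))
  psd_median_freq(s$freq, s$psd, band)
}

## Median of a discrete spectral power distribution with interpolated
## crossings and plateau-midpoint tie handling.
psd_median_freq <- function(freq, psd, band, tol = 1e-9) {
  sel <- freq >= band[1] & freq <= band[2]
  f <- freq[sel]
  p <- psd[sel]
  tot <- sum(p)
  if (length(f) < 2 || tot <= 0) return(NA_real_)
  cs <- cumsum(p)
  half <- tot / 2
  eps <- tol * tot
  i <- which(cs >= half - eps)[1]
  lo <- if (i == 1) f[1] else {
    frac <- (half - cs[i - 1]) / (cs[i] - cs[i - 1])
    f[i - 1] + (f[i] - f[i - 1]) * min(1, max(0, frac))
  }
  csb <- c(0, cs[-length(cs)])
  j <- tail(which(csb <= half + eps), 1)
  hi <- if (j == length(f)) f[length(f)] else {
    frac <- (half - csb[j]) / (csb[j + 1] - csb[j])
    f[j] + (f[j + 1] - f[j]) * min(1, max(0, frac))
  }
  (lo + hi) / 2
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts pairs of length-`m`
#' templates within Chebyshev distance `r` and `A` counts the pairs still
#' matching when extended to length `m + 1`; self-matches are excluded and
#' both template sets share the same `n - m` offsets (Richman-Moorman
#' convention).  The tolerance is relative: `r = r_factor * sd(x)`, making
#' the statistic invariant under affine transforms of the signal.  Lower
#' values indicate more regular, more predictable activity.
#'
#' When `band` and `fs` are supplied the window is re-filtered to that band
#' first (the EHG convention computes SampEn on the 0.34-4 Hz
#' fast-wave-high component); the tolerance is taken from the SD of the
#' re-filtered window.
#'
#' @param x numeric vector (window).
#' @param m template length (default 2).
#' @param r_factor tolerance as a fraction of the window SD (default 0.2).
#' @param fs sampling rate in Hz; only needed when `band` is given.
#' @param band optional band in Hz to re-filter to before computing.
#' @return Sample entropy (non-negative), or `NA` when no template pairs
#'   match (`B = 0` or `A = 0`) or the window is constant.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, fs = NULL, band = NULL) {
  x <- as.numeric(x)
  if (!is.null(band)) {
    if (is.null(fs)) stopf("`fs` is required when `band` is given")
    x <- fft_bandpass(x, fs, band[1], band[2])
  }
  n <- length(x)
  if (n < m + 2) stopf("need at least m + 2 samples (n = %d, m = %d)", n, m)
  s <- sd(x)
  if (!is.finite(s) || s <= 0) return(NA_real_)
  cnt <- .sampen_counts(x, as.integer(m), r_factor * s)
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[2] / cnt[1])
}

#' Per-window feature table
#'
#' Computes the four whole-window features for every analysis window:
#' PPA and KHE on the window as given (0.1-4 Hz), MDF restricted to
#' `mdf_band`, and SampEn on the window re-filtered to `sampen_band`.
#' Undefined features are returned as `NA` and later excluded per feature
#' at aggregation — never imputed.
#'
#' @param windows an `ehg_windows` object from [segment_windows()].
#' @param mdf_band band for [median_frequency()] (Hz).
#' @param sampen_band band the window is re-filtered to for
#'   [sample_entropy()] (Hz).
#' @param m,r_factor sample-entropy parameters.
#' @return A data frame with columns `start_s`, `ppa`, `khe`, `mdf`,
#'   `sampen`, one row per window.
#' @export
window_features <- function(windows, mdf_band = c(0.2, 1.0),
                            sampen_band = c(0.34, 4.0), m = 2,
                            r_factor = 0.2) {
  stopifnot(inherits(windows, "ehg_windows"))
  nw <- nrow(windows$samples)
  out <- data.frame(start_s = windows$start_s,
                    ppa = rep(NA_real_, nw), khe = rep(NA_real_, nw),
                    mdf = rep(NA_real_, nw), sampen = rep(NA_real_, nw))
  for (i in seq_len(nw)) {
    w <- windows$samples[i, ]
    out$ppa[i] <- peak_to_peak(w)
    out$khe[i] <- hilbert_envelope_kurtosis(w, windows$fs)
    out$mdf[i] <- median_frequency(w, windows$fs, band = mdf_band)
    out$sampen[i] <- sample_entropy(w, m = m, r_factor = r_factor,
                                    fs = windows$fs, band = sampen_band)
  }
  out
}

#' Aggregate window features to one row per recording
#'
#' The median across windows represents the recording; undefined (`NA`)
#' windows are excluded per feature.  Medians are robust to occasional
#' outlier windows and invariant to window order.
#'
#' @param features a data frame from [window_features()].
#' @param metadata a list or one-row data frame with `recording_id`,
#'   `woman_id`, `ga_wog`, `gestation_type`, `stage_label` (e.g. an
#'   [ehg_recording()]).
#' @return A one-row data frame (`RecordingSummary`): metadata plus
#'   `median_ppa`, `median_khe`, `median_mdf`, `median_sampen`,
#'   `n_windows`.
#' @export
summarize_recording <- function(features, metadata = list()) {
  if (nrow(features) == 0L)
    stopf("no analysis windows: recording must be excluded")
  med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  getm <- function(f, d) {
    v <- metadata[[f]]
    if (is.null(v) || length(v) == 0L) d else v
  }
  data.frame(
    recording_id = as.character(getm("recording_id", NA_character_)),
    woman_id = as.character(getm("woman_id", NA_character_)),
    ga_wog = as.numeric(getm("ga_wog", NA_real_)),
    gestation_type = as.character(getm("gestation_type", NA_character_)),
    stage_label = as.character(getm("stage_label", NA_character_)),
    median_ppa = med(features$ppa),
    median_khe = med(features$khe),
    median_mdf = med(features$mdf),
    median_sampen = med(features$sampen),
    n_windows = nrow(features),
    stringsAsFactors = FALSE)
}

#' Preprocess and summarise one recording
#'
#' Convenience wrapper: [preprocess_recording()] then [window_features()]
#' then [summarize_recording()].
#'
#' @inheritParams preprocess_recording
#' @inheritParams window_features
#' @return A one-row recording summary, or `NULL` (with a warning) when
#'   the recording yields no analysis windows.
#' @export
extract_recording_summary <- function(recording,
                                      annotations = ehg_annotations(),
                                      low_hz = 0.1, high_hz = 4.0,
                                      target_fs = 20, window_s = 120,
                                      overlap = 0.5, mdf_band = c(0.2, 1.0),
                                      sampen_band = c(0.34, 4.0), m = 2,
                                      r_factor = 0.2) {
  win <- preprocess_recording(recording, annotations, low_hz, high_hz,
                              target_fs, window_s, overlap)
  if (nrow(win$samples) == 0L) {
    warning(sprintf("recording %s excluded: no artifact-free windows",
                    recording$recording_id), call. = FALSE)
    return(NULL)
  }
  feats <- window_features(win, mdf_band, sampen_band, m, r_factor)
  summarize_recording(feats, recording)
}

#' Build a cohort table from a list of recordings
#'
#' Runs the full preprocessing + feature pipeline on each recording and
#' stacks the per-recording summaries into a cohort table.  Recordings with
#' no artifact-free windows are dropped with a warning.
#'
#' @param recordings a list of [ehg_recording()] objects.
#' @param annotations optional list of [ehg_annotations()], parallel to
#'   `recordings` (or named by recording id).
#' @param ... passed on to [extract_recording_summary()].
#' @return A cohort data frame, one row per retained recording.
#' @export
extract_cohort_features <- function(recordings, annotations = NULL, ...) {
  rows <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    ann <- ehg_annotations()
    if (!is.null(annotations)) {
      ann <- if (!is.null(names(annotations))) annotations[[rec$recording_id]]
             else annotations[[i]]
      if (is.null(ann)) ann <- ehg_annotations()
    }
    s <- extract_recording_summary(rec, ann, ...)
    if (!is.null(s)) rows[[length(rows) + 1]] <- s
  }
  if (length(rows) == 0L) stopf("no recording produced any analysis window")
  do.call(rbind, rows)
}
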