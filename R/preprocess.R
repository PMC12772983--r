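#' Zero-phase band-pass filter a recording
#'
#' Keeps the physiologically meaningful EHG fast-wave components
#' (default 0.1-4 Hz), removing baseline drift below the low edge and
#' high-frequency noise above the high edge.  The filter is the squared
#' magnitude of a 5th-order Butterworth band-pass applied in the frequency
#' domain, which is the zero-phase (forward-backward) realisation: no group
#' delay, so feature timing is undistorted.  Expect edge transients within
#' roughly the first and last 10 s.
#'
#' @param recording an [ehg_recording()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth prototype order (per pass).
#' @return A filtered [ehg_recording()] of identical length.
#' @export
bandpass_filter <- function(recording, low_hz = 0.1, high_hz = 4.0, order = 5) {
  stopifnot(inherits(recording, "ehg_recording"))
  if (!(low_hz > 0 && low_hz < high_hz))
    stopf("band edges must satisfy 0 < low_hz < high_hz")
  if (high_hz >= recording$fs / 2)
    stopf("high_hz (%.3g) must be below the Nyquist frequency %.3g Hz",
          high_hz, recording$fs / 2)
  out <- recording
  out$samples <- fft_bandpass(recording$samples, recording$fs,
                              low_hz, high_hz, order)
  out
}

#' Resample a recording to a lower rate
#'
#' Anti-aliased Fourier resampling: the spectrum is truncated at the target
#' Nyquist frequency with a raised-cosine taper from 70% to 90% of it, then
#' inverted at the new length `round(n * target_fs / fs)`.  In-band content
#' (well below 0.7 x Nyquist) is preserved essentially exactly.
#'
#' @param recording an [ehg_recording()].
#' @param target_fs target sampling rate in Hz; must be below `fs` and
#'   above twice the 4 Hz EHG band edge.
#' @return A resampled [ehg_recording()].
#' @export
resample_to <- function(recording, target_fs = 20) {
  stopifnot(inherits(recording, "ehg_recording"))
  if (target_fs >= recording$fs)
    stopf("target_fs (%g) must be below the original rate (%g)",
          target_fs, recording$fs)
  if (target_fs <= 8)
    stopf("target_fs must exceed 8 Hz to cover the 0.1-4 Hz EHG band")
  out <- recording
  out$samples <- fft_resample(recording$samples, recording$fs, target_fs)
  out$fs <- target_fs
  out
}

#' Split a recording into artifact-free segments
#'
#' Removes all samples falling inside the annotated half-open intervals and
#' returns the maximal artifact-free stretches.  A sample at time
#' `t = (i - 1) / fs` is excluded iff `start_s <= t < end_s` for some
#' interval.  The segments partition the complement of the annotations:
#' summed clean samples plus excluded samples equal the recording length
#' exactly.
#'
#' @param recording an [ehg_recording()].
#' @param annotations an [ehg_annotations()] object (may be empty).
#' @return A list of clean segments, each a list with `samples`, `fs` and
#'   `offset_s` (seconds from the original recording start).
#' @export
exclude_artifacts <- function(recording, annotations = ehg_annotations()) {
  stopifnot(inherits(recording, "ehg_recording"))
  if (!inherits(annotations, "ehg_annotations"))
    annotations <- ehg_annotations(annotations$start_s, annotations$end_s)
  n <- length(recording$samples)
  fs <- recording$fs
  dur <- n / fs
  if (nrow(annotations) > 0 && any(annotations$end_s > dur + 1 / fs))
    stopf("annotation interval ends at %.3f s, beyond the recording (%.3f s)",
          max(annotations$end_s), dur)
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(annotations))) {
    ## 0-based sample k (time k / fs) is excluded iff start <= k/fs < end;
    ## computed on indices with a small guard so float noise at interval
    ## bounds cannot shift the cut by a sample
    i0 <- max(0L, as.integer(ceiling(annotations$start_s[i] * fs - 1e-6)))
    i1 <- min(n - 1L, as.integer(ceiling(annotations$end_s[i] * fs - 1e-6)) - 1L)
    if (i1 >= i0) keep[(i0 + 1L):(i1 + 1L)] <- FALSE
  }
  if (!any(keep)) return(list())
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    out[[length(out) + 1]] <- list(
      samples = recording$samples[starts[i]:ends[i]],
      fs = fs,
      offset_s = (starts[i] - 1) / fs)
  }
  out
}

#' Cut fixed-length analysis windows from clean segments
#'
#' Sliding windows of `window_s` seconds advanced by
#' `window_s * (1 - overlap)` within each clean segment.  Windows never
#' span an annotated artifact: a segment shorter than one window yields no
#' windows, and no window is patched across segment boundaries.
#'
#' @param segments a list of clean segments as returned by
#'   [exclude_artifacts()], or a single [ehg_recording()] (treated as one
#'   clean segment).
#' @param window_s window length in seconds (default 120).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return An object of class `ehg_windows`: a list with `samples` (matrix,
#'   one row per window), `fs`, and `start_s` (window starts in seconds
#'   from the original recording start).
#' @export
segment_windows <- function(segments, window_s = 120, overlap = 0.5) {
  if (inherits(segments, "ehg_recording"))
    segments <- list(list(samples = segments$samples, fs = segments$fs,
                          offset_s = 0))
  if (!(overlap >= 0 && overlap < 1)) stopf("`overlap` must be in [0, 1)")
  if (window_s <= 0) stopf("`window_s` must be positive")
  if (length(segments) == 0L)
    return(structure(list(samples = matrix(numeric(), 0, 0), fs = NA_real_,
                          start_s = numeric()), class = "ehg_windows"))
  fs <- segments[[1]]$fs
  len <- round(window_s * fs)
  step <- max(1L, round(window_s * (1 - overlap) * fs))
  rows <- list()
  start_s <- numeric()
  for (seg in segments) {
    stopifnot(seg$fs == fs)
    n <- length(seg$samples)
    if (n < len) next
    nw <- floor((n - len) / step) + 1
    for (w in seq_len(nw)) {
      i0 <- (w - 1) * step + 1
      rows[[length(rows) + 1]] <- seg$samples[i0:(i0 + len - 1)]
      start_s <- c(start_s, seg$offset_s + (i0 - 1) / fs)
    }
  }
  samples <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(), 0, len)
  structure(list(samples = samples, fs = fs, start_s = start_s),
            class = "ehg_windows")
}

#' @export
print.ehg_windows <- function(x, ...) {
  cat(sprintf("<ehg_windows> %d windows of %d samples at %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Band-pass filter at the original rate, resample, exclude annotated
#' artifacts, and cut analysis windows — in that order.
#'
#' @inheritParams bandpass_filter
#' @inheritParams resample_to
#' @inheritParams segment_windows
#' @param annotations an [ehg_annotations()] object (intervals in seconds
#'   of the *original* recording).
#' @return An `ehg_windows` object (see [segment_windows()]).
#' @export
preprocess_recording <- function(recording, annotations = ehg_annotations(),
                                 low_hz = 0.1, high_hz = 4.0, target_fs = 20,
                                 window_s = 120, overlap = 0.5) {
  rec <- bandpass_filter(recording, low_hz, high_hz)
  if (target_fs < rec$fs) rec <- resample_to(rec, target_fs)
  segs <- exclude_artifacts(rec, annotations)
  segment_windows(segs, window_s = window_s, overlap = overlap)
}
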