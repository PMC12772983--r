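#' Construct an EHG recording
#'
#' Container for one channel of uterine surface potential together with its
#' sampling rate and cohort metadata.  Amplitudes are in arbitrary units:
#' every downstream feature is either unit-agnostic (KHE, MDF, SampEn) or
#' scales linearly with the input (PPA), so no calibration is assumed.
#'
#' @param samples numeric vector of signal values.
#' @param fs sampling rate in Hz (positive).
#' @param recording_id,woman_id identifiers (coerced to character).
#' @param ga_wog gestational age at recording, in decimal weeks of
#'   gestation; `NA` allowed.
#' @param gestation_type `"SG"` (singleton) or `"MG"` (multiple/twin), or
#'   `NA`.
#' @param stage_label optional clinical stage: `"routine"` (prenatal
#'   check-up), `"TNL"` (term not in labour) or `"APL"` (active phase of
#'   labour).
#' @return An object of class `ehg_recording`.
#' @export
ehg_recording <- function(samples, fs, recording_id = NA_character_,
                          woman_id = NA_character_, ga_wog = NA_real_,
                          gestation_type = NA_character_,
                          stage_label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stopf("a recording needs at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stopf("`fs` must be a single positive number")
  if (!is.na(ga_wog) && ga_wog <= 0) stopf("`ga_wog` must be positive")
  if (!is.na(gestation_type) && !gestation_type %in% c("SG", "MG"))
    stopf("`gestation_type` must be \"SG\" or \"MG\"")
  if (!is.na(stage_label) && !stage_label %in% c("routine", "TNL", "APL"))
    stopf("`stage_label` must be \"routine\", \"TNL\" or \"APL\"")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         recording_id = as.character(recording_id),
         woman_id = as.character(woman_id),
         ga_wog = as.numeric(ga_wog),
         gestation_type = as.character(gestation_type),
         stage_label = as.character(stage_label)),
    class = "ehg_recording")
}

#' @export
print.ehg_recording <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ehg_recording> %s: %.1f s at %g Hz (%d samples)\n",
              x$recording_id, dur, x$fs, length(x$samples)))
  if (!is.na(x$ga_wog))
    cat(sprintf("  woman %s, GA %.1f WoG, %s, stage %s\n",
                x$woman_id, x$ga_wog, x$gestation_type, x$stage_label))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an [ehg_recording()].
#' @return Length in seconds (`n_samples / fs`).
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "ehg_recording"))
  length(recording$samples) / recording$fs
}

#' Normalize artifact-interval annotations
#'
#' Intervals are half-open `[start_s, end_s)` in seconds from recording
#' start.  Normalization sorts them, merges overlapping or touching
#' intervals, and validates `0 <= start < end`.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @return An object of class `ehg_annotations`: a data frame with columns
#'   `start_s`, `end_s`, sorted and non-overlapping.
#' @export
ehg_annotations <- function(start_s = numeric(), end_s = numeric()) {
  if (length(start_s) != length(end_s))
    stopf("`start_s` and `end_s` must have the same length")
  if (length(start_s) == 0L)
    return(structure(data.frame(start_s = numeric(), end_s = numeric()),
                     class = c("ehg_annotations", "data.frame")))
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
    stopf("annotation bounds must be finite")
  if (any(start_s < 0)) stopf("annotation intervals must start at or after 0")
  if (any(end_s <= start_s)) stopf("annotation intervals must satisfy start < end")
  o <- order(start_s, end_s)
  s <- start_s[o]; e <- end_s[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(); out_e <- numeric()
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] <= me) me <- max(me, e[i])
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  structure(data.frame(start_s = out_s, end_s = out_e),
            class = c("ehg_annotations", "data.frame"))
}

annotated_duration <- function(annotations) {
  if (nrow(annotations) == 0L) return(0)
  sum(annotations$end_s - annotations$start_s)
}

#' Read / write single-channel signal CSV
#'
#' The on-disk format is a two-column CSV (`time_s`, `value`).  Metadata
#' columns are not stored in the signal file; supply them to
#' `read_signal_csv()` or keep them in the cohort table.
#'
#' @param recording an [ehg_recording()].
#' @param path file path.
#' @param ... metadata fields passed on to [ehg_recording()] when reading.
#' @return `read_signal_csv()` returns an [ehg_recording()];
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
write_signal_csv <- function(recording, path) {
  stopifnot(inherits(recording, "ehg_recording"))
  n <- length(recording$samples)
  df <- data.frame(time_s = (0:(n - 1)) / recording$fs,
                   value = recording$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path, ...) {
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stopf("signal CSV must have columns time_s, value")
  if (nrow(df) < 2) stopf("signal CSV must contain at least two samples")
  fs <- 1 / median(diff(df$time_s))
  ehg_recording(df$value, fs = fs, ...)
}

#' Read / write artifact annotation CSV
#'
#' Two-column CSV (`start_s`, `end_s`), half-open intervals in seconds.
#'
#' @param annotations an [ehg_annotations()] object.
#' @param path file path.
#' @return `read_annotations_csv()` returns an [ehg_annotations()] object.
#' @export
write_annotations_csv <- function(annotations, path) {
  stopifnot(inherits(annotations, "ehg_annotations"))
  write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("start_s", "end_s") %in% names(df)))
    stopf("annotation CSV must have columns start_s, end_s")
  ehg_annotations(df$start_s, df$end_s)
}

#' Read / write a cohort table CSV
#'
#' A cohort table holds one row per recording with at least
#' `recording_id`, `woman_id`, `ga_wog`, `gestation_type` and
#' `stage_label`; feature summaries add `median_ppa`, `median_khe`,
#' `median_mdf`, `median_sampen` and `n_windows`.
#'
#' @param cohort a data frame.
#' @param path file path.
#' @return `read_cohort_csv()` returns a data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "woman_id", "ga_wog", "gestation_type")
  if (!all(need %in% names(df)))
    stopf("cohort CSV must have columns %s", paste(need, collapse = ", "))
  df
}
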