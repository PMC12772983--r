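#' Stratified dynamic downsampling for gestational-age balance
#'
#' Removes the systematic gestational-age imbalance between the singleton
#' and multiple-gestation recording sets before any between-group
#' statistics: GA is segmented into fixed-width bins and, within each bin,
#' the larger group is randomly downsampled (seeded, without replacement)
#' to the smaller group's count.  Bins where one group has no recordings
#' are dropped from both groups — an unmatched stratum cannot support a
#' between-group contrast.  Retained rows are returned unchanged.
#'
#' @param cohort a cohort data frame with at least `recording_id`,
#'   `ga_wog` and `gestation_type` columns.
#' @param bin_width_wog bin width in weeks (default 1, the natural
#'   clinical unit).
#' @param seed integer seed; bins are processed in ascending GA order so
#'   the same seed always removes the same recordings.
#' @return A list with `cohort` (the balanced table) and `report`
#'   (class `ehg_balance_report`): bin edges, per-bin before/after counts
#'   per group, removed recording ids, and the seed.
#' @export
stratified_dynamic_sampling <- function(cohort, bin_width_wog = 1.0,
                                        seed = 1L) {
  need <- c("recording_id", "ga_wog", "gestation_type")
  if (!all(need %in% names(cohort)))
    stopf("cohort must have columns %s", paste(need, collapse = ", "))
  if (any(is.na(cohort$ga_wog)) || any(is.na(cohort$gestation_type)))
    stopf("cohort has missing ga_wog or gestation_type")
  if (bin_width_wog <= 0) stopf("`bin_width_wog` must be positive")
  groups <- c("SG", "MG")
  if (!all(cohort$gestation_type %in% groups))
    stopf("gestation_type must be SG or MG")
  if (any(!groups %in% cohort$gestation_type))
    stopf("both SG and MG must be present")
  lo <- floor(min(cohort$ga_wog) / bin_width_wog) * bin_width_wog
  hi <- max(cohort$ga_wog)
  edges <- seq(lo, hi + bin_width_wog, by = bin_width_wog)
  bin <- findInterval(cohort$ga_wog, edges, rightmost.closed = FALSE)
  removed <- character()
  keep <- rep(TRUE, nrow(cohort))
  before <- after <- matrix(0L, nrow = length(edges) - 1, ncol = 2,
                            dimnames = list(NULL, groups))
  with_seed(seed, {
    for (b in sort(unique(bin))) {
      idx <- which(bin == b)
      counts <- vapply(groups, function(g)
        sum(cohort$gestation_type[idx] == g), integer(1))
      before[b, ] <- counts
      if (any(counts == 0L)) {
        keep[idx] <- FALSE
        removed <- c(removed, cohort$recording_id[idx])
        next
      }
      target <- min(counts)
      after[b, ] <- target
      for (g in groups) {
        gi <- idx[cohort$gestation_type[idx] == g]
        if (length(gi) > target) {
          drop <- sample(gi, length(gi) - target)
          keep[drop] <- FALSE
          removed <- c(removed, cohort$recording_id[drop])
        }
      }
    }
  })
  report <- structure(
    list(bin_edges = edges, before = before, after = after,
         removed_ids = removed, bin_width_wog = bin_width_wog,
         seed = as.integer(seed)),
    class = "ehg_balance_report")
  list(cohort = cohort[keep, , drop = FALSE], report = report)
}

#' @export
print.ehg_balance_report <- function(x, ...) {
  cat(sprintf("<ehg_balance_report> %d bins of %.2g WoG, %d recordings removed (seed %d)\n",
              nrow(x$before), x$bin_width_wog, length(x$removed_ids), x$seed))
  shown <- rowSums(x$before) > 0
  df <- data.frame(bin = sprintf("[%g, %g)", head(x$bin_edges, -1)[shown],
                                 x$bin_edges[-1][shown]),
                   SG_before = x$before[shown, "SG"],
                   MG_before = x$before[shown, "MG"],
                   SG_after = x$after[shown, "SG"],
                   MG_after = x$after[shown, "MG"])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a balance report as JSON
#' @param report an `ehg_balance_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_balance_report <- function(report, path) {
  stopifnot(inherits(report, "ehg_balance_report"))
  jsonlite::write_json(
    list(bin_edges = report$bin_edges,
         before = as.data.frame(report$before),
         after = as.data.frame(report$after),
         removed_ids = report$removed_ids,
         bin_width_wog = report$bin_width_wog, seed = report$seed),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
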