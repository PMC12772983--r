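ehg_features <- c(ppa = "median_ppa", khe = "median_khe",
                  mdf = "median_mdf", sampen = "median_sampen")

#' Run the full trend analysis on a cohort table
#'
#' Reproduces the study layout end-to-end on a cohort of per-recording
#' feature summaries:
#'
#' 1. stage stratification ([stratify_by_stage()]);
#' 2. gestational-age balancing of the routine SG/MG recordings
#'    ([stratified_dynamic_sampling()]); term recordings (TNL/APL) have no
#'    MG counterpart and are kept aside from balancing;
#' 3. per-feature, per-group GAM trend curves with 95% confidence bands
#'    ([fit_gam_trend()]);
#' 4. per-feature, per-group Spearman correlations with GA
#'    ([spearman_ga_correlation()]); for SG the correlation optionally
#'    spans the full range including TNL/APL recordings
#'    (`include_term = TRUE`), while MG is restricted to routine
#'    recordings before 37 WoG;
#' 5. Wilcoxon rank-sum comparisons ([wilcoxon_compare()]): SG vs MG
#'    within each routine stage, and across stages within each gestation
#'    type.
#'
#' Raw p-values are reported at `alpha` with no multiple-testing
#' correction, matching standard practice in this literature.  Missing
#' groups or stages degrade gracefully: the affected results are omitted
#' and logged in `$log`.
#'
#' @param cohort a cohort data frame (e.g. from
#'   [extract_cohort_features()]) with metadata and `median_*` feature
#'   columns.
#' @param alpha significance level.
#' @param balance logical: apply GA balancing to the routine recordings.
#' @param bin_width_wog balancing bin width in weeks.
#' @param include_term include TNL/APL recordings in the SG correlations
#'   and trends.
#' @param grid_step GA grid spacing for trend curves (weeks).
#' @param k GAM basis dimension.
#' @param seed seed for the balancing step.
#' @return An object of class `ehg_analysis`: `cohort` (stratified,
#'   balanced), `balance_report`, `trends` (named list of
#'   `ehg_trend_fit`), `correlations` and `comparisons` (data frames),
#'   `alpha`, `log`.
#' @export
run_full_analysis <- function(cohort, alpha = 0.05, balance = TRUE,
                              bin_width_wog = 1.0, include_term = TRUE,
                              grid_step = 0.25, k = 10, seed = 1L) {
  feats <- ehg_features[ehg_features %in% names(cohort)]
  if (length(feats) == 0L)
    stopf("cohort has no median_* feature columns")
  cohort <- stratify_by_stage(cohort)
  log <- character()
  routine <- cohort[cohort$stage %in% c("Early3T", "Late3T"), , drop = FALSE]
  term <- cohort[cohort$stage %in% c("TNL", "APL"), , drop = FALSE]
  report <- NULL
  if (balance && all(c("SG", "MG") %in% routine$gestation_type)) {
    bal <- stratified_dynamic_sampling(routine, bin_width_wog, seed)
    routine <- bal$cohort
    report <- bal$report
  } else if (balance) {
    log <- c(log, "balancing skipped: only one gestation type present")
  }
  cohort <- rbind(routine, term)
  if (anyDuplicated(cohort$woman_id[cohort$stage %in% c("Early3T", "Late3T")]))
    log <- c(log,
             "repeated recordings per woman treated as independent (recording-level analysis)")

  sg_rows <- function(with_term) {
    r <- cohort[cohort$gestation_type == "SG", , drop = FALSE]
    if (!with_term) r <- r[r$stage %in% c("Early3T", "Late3T"), , drop = FALSE]
    r
  }
  mg_rows <- cohort[cohort$gestation_type == "MG" &
                    cohort$stage %in% c("Early3T", "Late3T"), , drop = FALSE]

  trends <- list()
  correlations <- list()
  for (f in names(feats)) {
    col <- feats[[f]]
    for (grp in c("SG", "MG")) {
      rows <- if (grp == "SG") sg_rows(include_term) else mg_rows
      if (nrow(rows) < 10) {
        log <- c(log, sprintf("%s/%s: too few recordings (%d), skipped",
                              f, grp, nrow(rows)))
        next
      }
      correlations[[paste(f, grp)]] <-
        spearman_ga_correlation(rows[[col]], rows$ga_wog, feature = f,
                                group = grp)
      tf <- tryCatch(
        fit_gam_trend(rows[[col]], rows$ga_wog, feature = f, group = grp,
                      k = k, grid_step = grid_step),
        error = function(e) {
          log <<- c(log, sprintf("%s/%s trend: %s", f, grp, conditionMessage(e)))
          NULL
        })
      if (!is.null(tf)) trends[[paste(f, grp, sep = ".")]] <- tf
    }
  }

  comparisons <- list()
  cmp <- function(rows_a, rows_b, col, f, label) {
    if (nrow(rows_a) < 3 || nrow(rows_b) < 3) {
      log <<- c(log, sprintf("%s %s: group too small, skipped", f, label))
      return(NULL)
    }
    wilcoxon_compare(rows_a[[col]], rows_b[[col]], alpha = alpha,
                     contrast = label, feature = f)
  }
  for (f in names(feats)) {
    col <- feats[[f]]
    ## family 1: SG vs MG within routine stage
    for (st in c("Early3T", "Late3T")) {
      a <- cohort[cohort$gestation_type == "SG" & cohort$stage == st, ]
      b <- cohort[cohort$gestation_type == "MG" & cohort$stage == st, ]
      comparisons[[length(comparisons) + 1]] <-
        cmp(a, b, col, f, sprintf("SG-%s vs MG-%s", st, st))
    }
    ## family 2: across stages within gestation type
    sg_stages <- c("Early3T", "Late3T", "TNL", "APL")
    present <- sg_stages[vapply(sg_stages, function(s)
      sum(cohort$gestation_type == "SG" & cohort$stage == s) >= 3, logical(1))]
    if (length(present) >= 2) {
      prs <- combn(present, 2)
      for (i in seq_len(ncol(prs))) {
        a <- cohort[cohort$gestation_type == "SG" & cohort$stage == prs[1, i], ]
        b <- cohort[cohort$gestation_type == "SG" & cohort$stage == prs[2, i], ]
        comparisons[[length(comparisons) + 1]] <-
          cmp(a, b, col, f, sprintf("SG-%s vs SG-%s", prs[1, i], prs[2, i]))
      }
    }
    a <- cohort[cohort$gestation_type == "MG" & cohort$stage == "Early3T", ]
    b <- cohort[cohort$gestation_type == "MG" & cohort$stage == "Late3T", ]
    if (nrow(a) >= 3 && nrow(b) >= 3)
      comparisons[[length(comparisons) + 1]] <-
        cmp(a, b, col, f, "MG-Early3T vs MG-Late3T")
  }
  comparisons <- comparisons[!vapply(comparisons, is.null, logical(1))]

  structure(
    list(cohort = cohort, balance_report = report, trends = trends,
         correlations = if (length(correlations))
           do.call(rbind, unname(correlations)) else NULL,
         comparisons = if (length(comparisons))
           do.call(rbind, comparisons) else NULL,
         alpha = alpha, include_term = include_term, log = log),
    class = "ehg_analysis")
}

#' @export
print.ehg_analysis <- function(x, ...) {
  cat(sprintf("<ehg_analysis> %d recordings (%d SG, %d MG), alpha = %g\n",
              nrow(x$cohort), sum(x$cohort$gestation_type == "SG"),
              sum(x$cohort$gestation_type == "MG"), x$alpha))
  cat(sprintf("  %d trend fits, %d correlations, %d comparisons\n",
              length(x$trends),
              if (is.null(x$correlations)) 0L else nrow(x$correlations),
              if (is.null(x$comparisons)) 0L else nrow(x$comparisons)))
  if (!is.null(x$correlations)) {
    cat("\nSpearman correlations with GA:\n")
    print(format(x$correlations, digits = 3), row.names = FALSE)
  }
  if (length(x$log)) cat("\nnotes:", paste(x$log, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
summary.ehg_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$comparisons)) {
    cat("\nWilcoxon rank-sum comparisons:\n")
    print(format(object$comparisons, digits = 3), row.names = FALSE)
  }
  invisible(object)
}

#' Plot the fitted gestational-age trends
#'
#' One panel per feature, SG in blue and MG in red, with shaded 95%
#' pointwise confidence bands and the per-recording points.
#'
#' @param x an `ehg_analysis` object.
#' @param features which features to draw.
#' @param ... ignored.
#' @export
plot.ehg_analysis <- function(x, features = c("ppa", "khe", "mdf", "sampen"),
                              ...) {
  features <- features[paste(features, "SG", sep = ".") %in% names(x$trends) |
                       paste(features, "MG", sep = ".") %in% names(x$trends)]
  if (length(features) == 0L) stopf("no fitted trends to plot")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(features)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- c(SG = "steelblue", MG = "firebrick")
  for (f in features) {
    col <- ehg_features[[f]]
    plot(x$cohort$ga_wog, x$cohort[[col]],
         col = grDevices::adjustcolor(cols[x$cohort$gestation_type], 0.4),
         pch = 16, cex = 0.6, xlab = "Gestational age (WoG)", ylab = f,
         main = toupper(f))
    for (grp in c("SG", "MG")) {
      tf <- x$trends[[paste(f, grp, sep = ".")]]
      if (!is.null(tf)) plot(tf, add = TRUE, col = cols[[grp]])
    }
    graphics::abline(v = 37, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Write analysis tables to a directory
#'
#' Emits `correlations.csv`, `comparisons.csv`, one `trend_<feature>_<group>.csv`
#' per fitted curve, `balance_report.json` (when balancing ran) and
#' `summary.json`.
#'
#' @param analysis an `ehg_analysis` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "ehg_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(analysis$correlations))
    write.csv(analysis$correlations, file.path(dir, "correlations.csv"),
              row.names = FALSE)
  if (!is.null(analysis$comparisons))
    write.csv(analysis$comparisons, file.path(dir, "comparisons.csv"),
              row.names = FALSE)
  for (nm in names(analysis$trends))
    write.csv(analysis$trends[[nm]]$grid,
              file.path(dir, sprintf("trend_%s.csv", gsub("\\.", "_", nm))),
              row.names = FALSE)
  if (!is.null(analysis$balance_report))
    write_balance_report(analysis$balance_report,
                         file.path(dir, "balance_report.json"))
  jsonlite::write_json(
    list(n_recordings = nrow(analysis$cohort), alpha = analysis$alpha,
         n_trends = length(analysis$trends), log = analysis$log),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
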