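#' Assign gestational-stage labels
#'
#' Routine check-up recordings are stratified at the clinical thresholds of
#' 32 and 37 weeks of gestation into `Early3T` (`GA < 32`) and `Late3T`
#' (`32 <= GA < 37`); both intervals are half-open.  Recordings flagged
#' `TNL` (term not in labour) or `APL` (active phase of labour) in the
#' metadata keep those labels regardless of GA — stage beyond 37 WoG is a
#' clinical determination, not a GA cut.  A routine recording at or beyond
#' 37 WoG is outside the scheme and raises an error.
#'
#' @param cohort a cohort data frame with `ga_wog` and (optionally)
#'   `stage_label` columns.
#' @return The cohort with a `stage` factor column
#'   (`Early3T`, `Late3T`, `TNL`, `APL`).
#' @export
stratify_by_stage <- function(cohort) {
  if (!"ga_wog" %in% names(cohort)) stopf("cohort must have a `ga_wog` column")
  ga <- cohort$ga_wog
  if (any(is.na(ga))) stopf("cohort has missing ga_wog")
  lab <- if ("stage_label" %in% names(cohort)) cohort$stage_label
         else rep(NA_character_, nrow(cohort))
  stage <- character(nrow(cohort))
  term <- !is.na(lab) & lab %in% c("TNL", "APL")
  stage[term] <- lab[term]
  routine <- !term
  bad <- routine & ga >= 37
  if (any(bad))
    stopf("routine recording(s) at GA >= 37 WoG without TNL/APL flag: %s",
          paste(cohort$recording_id[bad], collapse = ", "))
  stage[routine & ga < 32] <- "Early3T"
  stage[routine & ga >= 32 & ga < 37] <- "Late3T"
  cohort$stage <- factor(stage, levels = c("Early3T", "Late3T", "TNL", "APL"))
  cohort
}

#' Spearman rank correlation between a feature and gestational age
#'
#' Rank correlation with average-rank tie handling and a two-sided
#' p-value: exact by full permutation enumeration for `n <= 7`, otherwise
#' the usual t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param values numeric feature values.
#' @param ga gestational ages (weeks), same length.
#' @param feature,group optional labels carried into the result.
#' @return A one-row data frame of class `ehg_correlation`: `feature`,
#'   `group`, `rho`, `p_value`, `n`, `method`.  Zero variance in either
#'   variable yields `NA` rho and p.
#' @export
spearman_ga_correlation <- function(values, ga, feature = NA_character_,
                                    group = NA_character_) {
  if (length(values) != length(ga)) stopf("inputs must have the same length")
  ok <- is.finite(values) & is.finite(ga)
  x <- values[ok]; g <- ga[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs (have %d)", n)
  res <- data.frame(feature = feature, group = group, rho = NA_real_,
                    p_value = NA_real_, n = n, method = NA_character_,
                    stringsAsFactors = FALSE)
  class(res) <- c("ehg_correlation", "data.frame")
  if (sd(x) == 0 || sd(g) == 0) return(res)
  res$rho <- rank_pearson(x, g)
  if (n <= 7) {
    perms <- perm_matrix(n)
    rhos <- apply(perms, 1, function(p) rank_pearson(x[p], g))
    res$p_value <- mean(abs(rhos) >= abs(res$rho) - 1e-12)
    res$method <- "exact permutation"
  } else {
    r <- res$rho
    t <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
    res$p_value <- min(1, 2 * pt(-abs(t), df = n - 2))
    res$method <- "t approximation"
  }
  res
}

## Pearson correlation of average ranks.
rank_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rx <- rx - mean(rx); ry <- ry - mean(ry)
  den <- sqrt(sum(rx^2) * sum(ry^2))
  if (den == 0) return(NA_real_)
  sum(rx * ry) / den
}

## All permutations of 1..n (n <= 7 in practice).
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(rep(i, nrow(sub)), sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney test: exact enumeration when the combined sample
#' size is at most `exact_max_n` and there are no ties, otherwise the
#' normal approximation with tie correction (and continuity correction).
#'
#' @param group_a,group_b numeric feature values.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param contrast optional description string carried into the result.
#' @param feature optional feature label.
#' @param exact_max_n largest combined n for exact enumeration.
#' @return A one-row data frame of class `ehg_comparison`: `feature`,
#'   `contrast`, `statistic` (Mann-Whitney U of the first group),
#'   `p_value`, `significant`, `n_a`, `n_b`, `method`.
#' @export
wilcoxon_compare <- function(group_a, group_b, alpha = 0.05,
                             contrast = NA_character_,
                             feature = NA_character_, exact_max_n = 20) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) == 0L || length(b) == 0L) stopf("empty group")
  if (length(a) < 3 || length(b) < 3)
    warning("fewer than 3 observations in a group; p-value unreliable",
            call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= exact_max_n) && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  res <- data.frame(feature = feature, contrast = contrast,
                    statistic = unname(ht$statistic), p_value = ht$p.value,
                    significant = ht$p.value < alpha,
                    n_a = length(a), n_b = length(b),
                    method = if (exact) "exact" else "normal approximation",
                    stringsAsFactors = FALSE)
  class(res) <- c("ehg_comparison", "data.frame")
  res
}

#' Fit a gestational-age trend with a generalized additive model
#'
#' One univariate penalized cubic regression spline smooth of the feature
#' on GA (Gaussian response, identity link, basis dimension `k`, smoothing
#' parameter chosen by generalized cross-validation via [mgcv::gam()]),
#' evaluated with 95% pointwise confidence bands on a uniform GA grid.
#'
#' @param values numeric feature values.
#' @param ga gestational ages in weeks.
#' @param feature,group optional labels carried on the fit.
#' @param k spline basis dimension (default 10).
#' @param grid_step GA grid spacing in weeks (default 0.25).
#' @param level confidence level for the pointwise band.
#' @return An object of class `ehg_trend_fit`: `grid` data frame
#'   (`ga`, `fit`, `lower`, `upper`), `edf`, `sp`, `n`, labels, and the
#'   underlying `mgcv` model.
#' @export
fit_gam_trend <- function(values, ga, feature = NA_character_,
                          group = NA_character_, k = 10, grid_step = 0.25,
                          level = 0.95) {
  ok <- is.finite(values) & is.finite(ga)
  y <- values[ok]; x <- ga[ok]
  if (length(y) < 10) stopf("need at least 10 observations for a GAM trend")
  if (diff(range(x)) < 1e-8) stopf("GA values span zero range")
  nu <- length(unique(x))
  if (nu < k + 1) {
    if (nu < 5)
      stopf("only %d unique GA values; too few for a spline basis — reduce `k`",
            nu)
    k <- nu - 1
  }
  df <- data.frame(y = y, x = x)
  fit <- mgcv::gam(y ~ s(x, bs = "cr", k = k), data = df,
                   method = "GCV.Cp")
  grid <- seq(min(x), max(x), by = grid_step)
  pr <- predict(fit, newdata = data.frame(x = grid), se.fit = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  structure(
    list(grid = data.frame(ga = grid, fit = as.numeric(pr$fit),
                           lower = as.numeric(pr$fit - z * pr$se.fit),
                           upper = as.numeric(pr$fit + z * pr$se.fit)),
         edf = sum(fit$edf) - 1, sp = unname(fit$sp), n = length(y),
         k = k, level = level, feature = feature, group = group,
         model = fit),
    class = "ehg_trend_fit")
}

#' @export
print.ehg_trend_fit <- function(x, ...) {
  cat(sprintf("<ehg_trend_fit> %s (%s): n = %d, edf = %.2f, GA %.1f-%.1f WoG\n",
              x$feature, x$group, x$n, x$edf, min(x$grid$ga), max(x$grid$ga)))
  invisible(x)
}

#' @export
predict.ehg_trend_fit <- function(object, ga, ...) {
  as.numeric(predict(object$model, newdata = data.frame(x = ga)))
}

#' @export
plot.ehg_trend_fit <- function(x, add = FALSE, col = "steelblue", ...) {
  g <- x$grid
  if (!add) {
    plot(g$ga, g$fit, type = "n", xlab = "Gestational age (WoG)",
         ylab = x$feature, ylim = range(g$lower, g$upper), ...)
  }
  graphics::polygon(c(g$ga, rev(g$ga)), c(g$lower, rev(g$upper)),
                    col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(g$ga, g$fit, col = col, lwd = 2)
  invisible(x)
}
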