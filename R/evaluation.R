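#' Per-sample deviation score from the control reference
#'
#' For a panel of metabolites, a sample's deviation score is the sum over
#' panel metabolites of the absolute difference from the control-cohort
#' week-0 median, normalized by the control-cohort week-0 standard
#' deviation: `D_i = sum_m |x_im - median_TD(m)| / sd_TD(m)`.  A sample
#' sitting exactly at the control medians scores 0; each metabolite one
#' control-SD away contributes 1.
#'
#' @param X numeric sample-by-panel matrix on the reference scale.
#' @param stats `reference_stats` from [normalize_to_reference()].
#' @param panel character vector of panel metabolite ids (must match the
#'   columns of `X`).
#' @return Non-negative numeric vector, one score per row of `X`.
#' @export
deviation_score <- function(X, stats, panel) {
  stopifnot(inherits(stats, "reference_stats"))
  X <- as.matrix(X)[, panel, drop = FALSE]
  missing <- setdiff(panel, stats$metabolite)
  if (length(missing))
    stop("feature misalignment: no reference stats for ",
         paste(missing, collapse = ", "))
  med <- stats$median[panel]
  sdv <- stats$sd[panel]
  if (any(sdv == 0))
    stop("degenerate reference spread: zero SD for ",
         paste(panel[sdv == 0], collapse = ", "))
  rowSums(sweep(abs(sweep(X, 2, med)), 2, sdv, "/"))
}

# inclusive (linear-interpolation) quartile summary
q_summary <- function(x) {
  q <- quantile(x, c(0.5, 0.25, 0.75), type = 7, na.rm = TRUE)
  c(median = unname(q[1L]), q25 = unname(q[2L]), q75 = unname(q[3L]))
}

#' Longitudinal trajectory of a discriminant panel
#'
#' Applies a fitted week-0 panel model across the treatment time points:
#' per week, the treated cohort's discriminant scores are projected, a
#' kernel density is refit to them, and the Type II error is the smoothed
#' CDF of that week's score density evaluated at the *fixed* week-0
#' threshold.  Alongside, the control-referenced deviation score (see
#' [deviation_score()]) is summarized per week -- per metabolite and
#' summed -- with medians and quartiles, including the control cohort's
#' own week-0 row as a baseline.
#'
#' @param model an [fit_fda()] model of the panel.
#' @param dataset the preprocessed [study_dataset] (all weeks on the
#'   reference scale).
#' @param stats `reference_stats` covering the panel.
#' @param threshold a `threshold_spec` placed on the week-0 treated-cohort
#'   density (its Type II error at week 0 reproduces `beta` by
#'   construction).
#' @param weeks weeks to evaluate (default all of 0, 3, 10, 18); weeks
#'   absent from the data are skipped with a warning.
#' @return An object of class `trajectory_report`: data frames `type2`
#'   (`week`, `type2_error`), `panel_scores` (deviation-score summaries per
#'   cohort-week), `metabolite_scores` (per-metabolite deviation
#'   summaries), the per-week score lists and densities, and the threshold.
#' @export
score_trajectory <- function(model, dataset, stats, threshold,
                             weeks = c(0L, 3L, 10L, 18L)) {
  stopifnot(inherits(model, "fda_model"),
            inherits(threshold, "threshold_spec"))
  panel <- model$metabolites
  have <- sort(unique(dataset$meta$week[dataset$meta$cohort == "ASD"]))
  skip <- setdiff(weeks, have)
  if (length(skip))
    warning("week(s) ", paste(skip, collapse = ", "),
            " absent from the treated cohort; omitted")
  weeks <- intersect(weeks, have)

  type2 <- numeric(length(weeks))
  scores <- densities <- vector("list", length(weeks))
  panel_rows <- list(); met_rows <- list()
  for (wi in seq_along(weeks)) {
    v <- select_samples(dataset, cohort = "ASD", week = weeks[wi])
    Xw <- view_values(v, panel)
    sc <- fda_project(model, Xw)
    dens <- fit_kde(sc)
    type2[wi] <- dens$cdf(threshold$threshold)
    scores[[wi]] <- sc
    densities[[wi]] <- dens
    D <- deviation_score(Xw, stats, panel)
    panel_rows[[length(panel_rows) + 1L]] <-
      data.frame(cohort = "ASD", week = weeks[wi], t(q_summary(D)))
    dev_terms <- sweep(abs(sweep(Xw, 2, stats$median[panel])), 2,
                       stats$sd[panel], "/")
    for (m in panel)
      met_rows[[length(met_rows) + 1L]] <-
        data.frame(metabolite = m, cohort = "ASD", week = weeks[wi],
                   t(q_summary(dev_terms[, m])))
  }
  # control-cohort baseline row
  td <- select_samples(dataset, cohort = "TD", week = 0L)
  Xtd <- view_values(td, panel)
  panel_rows[[length(panel_rows) + 1L]] <-
    data.frame(cohort = "TD", week = 0L,
               t(q_summary(deviation_score(Xtd, stats, panel))))
  dev_td <- sweep(abs(sweep(Xtd, 2, stats$median[panel])), 2,
                  stats$sd[panel], "/")
  for (m in panel)
    met_rows[[length(met_rows) + 1L]] <-
      data.frame(metabolite = m, cohort = "TD", week = 0L,
                 t(q_summary(dev_td[, m])))

  names(scores) <- names(densities) <- paste0("week", weeks)
  structure(list(
    type2 = data.frame(week = weeks, type2_error = type2),
    panel_scores = do.call(rbind, panel_rows),
    metabolite_scores = do.call(rbind, met_rows),
    scores = scores, densities = densities,
    threshold = threshold, metabolites = panel),
    class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("<trajectory_report> panel: ",
      paste(x$metabolites, collapse = ", "), "\n", sep = "")
  cat("Type II error at the fixed week-0 threshold (beta = ",
      x$threshold$beta, "):\n", sep = "")
  print(x$type2, row.names = FALSE)
  cat("Summed deviation score (median [q25, q75]):\n")
  print(x$panel_scores, row.names = FALSE)
  invisible(x)
}

#' Percent reduction of the panel's gap to the control cohort
#'
#' Several natural summaries of "how much closer the treated cohort moved
#' to the control cohort" between two weeks are available; the method used
#' is always reported alongside the number.
#' \describe{
#'   \item{`median_of_sums`}{percent decrease of the median summed
#'     deviation score.}
#'   \item{`sum_of_medians`}{percent decrease of the sum over panel
#'     metabolites of the median per-metabolite deviation.}
#'   \item{`mean_abs_median_gap`}{percent decrease of the mean over panel
#'     metabolites of |treated median - control median| / control SD.}
#' }
#'
#' @param report a [score_trajectory()] report.
#' @param dataset,stats the inputs used for the report (needed for
#'   `mean_abs_median_gap`).
#' @param from,to weeks compared (defaults 0 and 18).
#' @param method one of the methods above.
#' @return List with `percent_decrease` and `method`.
#' @export
panel_gap_reduction <- function(report, dataset = NULL, stats = NULL,
                                from = 0L, to = 18L,
                                method = c("median_of_sums",
                                           "sum_of_medians",
                                           "mean_abs_median_gap")) {
  method <- match.arg(method)
  ps <- report$panel_scores
  ms <- report$metabolite_scores
  val <- switch(method,
    median_of_sums = {
      a <- ps$median[ps$cohort == "ASD" & ps$week == from]
      b <- ps$median[ps$cohort == "ASD" & ps$week == to]
      100 * (a - b) / a
    },
    sum_of_medians = {
      a <- sum(ms$median[ms$cohort == "ASD" & ms$week == from])
      b <- sum(ms$median[ms$cohort == "ASD" & ms$week == to])
      100 * (a - b) / a
    },
    mean_abs_median_gap = {
      stopifnot(!is.null(dataset), !is.null(stats))
      panel <- report$metabolites
      gap <- function(w) {
        Xw <- view_values(select_samples(dataset, cohort = "ASD", week = w),
                          panel)
        mean(abs(apply(Xw, 2, median) - stats$median[panel]) /
               stats$sd[panel])
      }
      a <- gap(from); b <- gap(to)
      100 * (a - b) / a
    })
  list(percent_decrease = unname(val), method = method)
}

#' Summarize the post-treatment shift of the top screened metabolites
#'
#' Over a set of top-ranked metabolites, reports (a) the percent with a
#' significant pre/post change test, (b) the count and percent whose
#' week-18 AUROC is strictly below their week-0 AUROC, and optionally
#' (c) the percent reduction in the mean absolute treated-control median
#' gap between the two weeks.
#'
#' @param week0_results data frame with columns `metabolite`,
#'   `auroc_week0` and `change_p` (`NA` where no significant p was
#'   recorded).
#' @param week18_aurocs named numeric vector of week-18 AUROCs.
#' @param alpha significance level for (a) (default 0.05).
#' @param week0_gaps,week18_gaps optional named numeric vectors of
#'   per-metabolite |treated median - control median| values for (c).
#' @return List: `n`, `pct_significant`, `n_lower`, `pct_lower`, and
#'   `pct_gap_reduction` (NA unless gaps are supplied).
#' @export
shift_summary <- function(week0_results, week18_aurocs, alpha = 0.05,
                          week0_gaps = NULL, week18_gaps = NULL) {
  if (is.null(week0_results) || nrow(week0_results) == 0L)
    stop("nothing to summarize")
  n <- nrow(week0_results)
  sig <- !is.na(week0_results$change_p) & week0_results$change_p < alpha
  a18 <- week18_aurocs[week0_results$metabolite]
  lower <- a18 < week0_results$auroc_week0
  gap_red <- NA_real_
  if (!is.null(week0_gaps) && !is.null(week18_gaps)) {
    g0 <- mean(abs(week0_gaps[week0_results$metabolite]), na.rm = TRUE)
    g18 <- mean(abs(week18_gaps[week0_results$metabolite]), na.rm = TRUE)
    gap_red <- 100 * (g0 - g18) / g0
  }
  list(n = n,
       pct_significant = 100 * mean(sig),
       n_lower = sum(lower, na.rm = TRUE),
       pct_lower = 100 * mean(lower, na.rm = TRUE),
       pct_gap_reduction = gap_red)
}
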