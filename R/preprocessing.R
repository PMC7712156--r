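#' Impute below-detection-limit values
#'
#' Every missing cell of a metabolite is replaced by the minimum observed
#' value of that metabolite divided by sqrt(2), the standard convention for
#' values censored at a detection limit.  Observed cells are untouched.
#'
#' @param dataset a [study_dataset] (may contain `NA` cells).
#' @return A [study_dataset] with no missing cells.
#' @export
impute_missing <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  v <- dataset$values
  nmiss <- colSums(is.na(v))
  if (any(nmiss == nrow(v)))
    stop("no observed values: metabolite(s) ",
         paste(colnames(v)[nmiss == nrow(v)], collapse = ", "),
         " are entirely missing")
  for (j in which(nmiss > 0)) {
    fill <- min(v[, j], na.rm = TRUE) / sqrt(2)
    v[is.na(v[, j]), j] <- fill
  }
  study_dataset(v, dataset$meta)
}

#' Detection-limit retention filter
#'
#' Applied to the week-0 samples of both cohorts (N samples).  The
#' detection limit of a metabolite is its minimum recorded value; a value
#' counts as "above the limit" only when strictly greater, so ties at the
#' minimum -- which are censored or imputed cells -- never count.  A
#' metabolite is retained when at least `floor(min_fraction * N)` week-0
#' values lie above its limit.
#'
#' When a metabolite still contains missing cells the limit is taken at
#' `min_observed / sqrt(2)`, the level that imputation would assign, so the
#' filter commutes with [impute_missing()].
#'
#' @param dataset a [study_dataset].
#' @param min_fraction minimum fraction of week-0 values that must exceed
#'   the detection limit (default 0.4).
#' @return An object of class `preprocess_report`: character vectors
#'   `retained` and `removed`, integer `qualifying_count` (the retention
#'   threshold), integer vector `above_limit` per metabolite, and `n` (the
#'   week-0 sample count).
#' @export
filter_detection_limit <- function(dataset, min_fraction = 0.4) {
  stopifnot(inherits(dataset, "study_dataset"))
  w0 <- select_samples(dataset, week = 0L)
  v <- view_values(w0)
  n <- nrow(v)
  if (n == 0L) stop("empty cohort")
  qual <- as.integer(floor(min_fraction * n))
  above <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    obs <- x[!is.na(x)]
    if (length(obs) == 0L) return(0L)
    dl <- if (anyNA(x)) min(obs) / sqrt(2) else min(obs)
    sum(obs > dl)
  }, integer(1))
  names(above) <- colnames(v)
  keep <- above >= qual
  structure(list(retained = colnames(v)[keep],
                 removed = colnames(v)[!keep],
                 qualifying_count = qual,
                 above_limit = above,
                 min_fraction = min_fraction,
                 n = n),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report> ", length(x$retained), " retained, ",
      length(x$removed), " removed (threshold: >= ", x$qualifying_count,
      " of ", x$n, " week-0 values above the detection limit)\n", sep = "")
  invisible(x)
}

#' Normalize abundances to the control-cohort week-0 median
#'
#' Divides every value of each metabolite -- at all weeks -- by the
#' metabolite's median over the reference view (the TD week-0 cohort), so
#' the reference median becomes exactly 1.0.  The same scale factors apply
#' to follow-up weeks, keeping all time points on the reference scale.
#'
#' @param dataset an imputed, filtered [study_dataset].
#' @param reference a `cohort_view` of the TD week-0 samples from
#'   [select_samples()].
#' @return A list: `dataset` (scaled [study_dataset]) and `stats`, an
#'   object of class `reference_stats` -- per-metabolite post-scaling
#'   reference `median` (identically 1) and sample standard deviation `sd`,
#'   plus the raw `scale` factors.
#' @export
normalize_to_reference <- function(dataset, reference) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(reference, "cohort_view"))
  ref <- view_values(reference)
  ref <- ref[, colnames(dataset$values), drop = FALSE]
  med <- apply(ref, 2, median, na.rm = TRUE)
  if (any(!is.finite(med)) || any(med <= 0))
    stop("degenerate reference: non-positive reference median for ",
         paste(colnames(ref)[!is.finite(med) | med <= 0], collapse = ", "))
  scaled <- sweep(dataset$values, 2, med, "/")
  ref_scaled <- sweep(ref, 2, med, "/")
  stats <- structure(list(
    metabolite = colnames(ref),
    median = rep(1, ncol(ref)),
    sd = apply(ref_scaled, 2, sd, na.rm = TRUE),
    scale = med), class = "reference_stats")
  names(stats$median) <- names(stats$sd) <- names(stats$scale) <- stats$metabolite
  list(dataset = study_dataset(scaled, dataset$meta), stats = stats)
}

#' Run the full preprocessing stage
#'
#' Convenience wrapper chaining [impute_missing()],
#' [filter_detection_limit()] (on week-0 samples) and
#' [normalize_to_reference()] (TD week-0 reference).
#'
#' @param dataset a raw [study_dataset].
#' @param min_fraction passed to [filter_detection_limit()].
#' @return A list: `dataset` (imputed, filtered, scaled), `stats`
#'   ([normalize_to_reference()]'s `reference_stats`) and `report` (the
#'   `preprocess_report`).
#' @export
preprocess_study <- function(dataset, min_fraction = 0.4) {
  imputed <- impute_missing(dataset)
  report <- filter_detection_limit(imputed, min_fraction)
  if (length(report$retained) == 0L)
    stop("empty cohort: no metabolite passed the detection-limit filter")
  kept <- keep_metabolites(imputed, report$retained)
  norm <- normalize_to_reference(kept,
                                 select_samples(kept, cohort = "TD", week = 0L))
  list(dataset = norm$dataset, stats = norm$stats, report = report)
}
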