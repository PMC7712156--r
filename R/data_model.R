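COHORT_LEVELS <- c("ASD", "TD")
WEEK_LEVELS <- c(0L, 3L, 10L, 18L)

#' Construct a longitudinal metabolomics study dataset
#'
#' Bundles a sample-by-metabolite relative-abundance matrix with per-sample
#' metadata (subject, cohort, collection week) and validates the study
#' invariants: one sample per subject and week, control (TD) samples only at
#' week 0, and non-negative abundances.  Below-detection-limit cells are
#' carried as `NA`, which is deliberately distinct from an abundance of 0.
#'
#' @param values numeric matrix, rows = samples, columns = metabolites.
#'   Row names (if present) must equal `meta$sample_id`.
#' @param meta data frame with columns `sample_id`, `subject_id`,
#'   `cohort` (one of `"ASD"`, `"TD"`) and `week` (one of 0, 3, 10, 18),
#'   one row per row of `values`.
#' @return An object of class `study_dataset` with elements `values` and
#'   `meta`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2", "m3")))
#' meta <- data.frame(sample_id = c("s1", "s2"),
#'                    subject_id = c("A", "B"),
#'                    cohort = c("ASD", "TD"), week = c(0L, 0L))
#' d <- study_dataset(m, meta)
#' dim(d$values)
#' @export
study_dataset <- function(values, meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "cohort", "week")
  if (!all(required %in% names(meta)))
    stop("invalid metadata: missing columns ",
         paste(setdiff(required, names(meta)), collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$subject_id <- as.character(meta$subject_id)
  meta$cohort <- as.character(meta$cohort)
  meta$week <- suppressWarnings(as.integer(meta$week))
  if (nrow(values) != nrow(meta))
    stop("invalid metadata: ", nrow(meta), " metadata rows for ",
         nrow(values), " sample rows")
  if (anyNA(meta$week) || !all(meta$week %in% WEEK_LEVELS))
    stop("invalid metadata: week must be one of ",
         paste(WEEK_LEVELS, collapse = ", "))
  if (!all(meta$cohort %in% COHORT_LEVELS))
    stop("invalid metadata: cohort must be one of ",
         paste(COHORT_LEVELS, collapse = ", "))
  key <- paste(meta$subject_id, meta$week, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate sample: more than one row for (",
         gsub("\r", ", week ", key[duplicated(key)][1L]), ")")
  if (any(meta$cohort == "TD" & meta$week != 0L))
    stop("invalid metadata: TD samples exist only at week 0")
  if (any(values < 0, na.rm = TRUE))
    stop("invalid value: negative abundance")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("met_%04d", seq_len(ncol(values)))
  rownames(values) <- meta$sample_id
  structure(list(values = values, meta = meta), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", nrow(x$values), " samples x ", ncol(x$values),
      " metabolites\n", sep = "")
  tab <- table(x$meta$cohort, x$meta$week)
  print(tab)
  nmiss <- sum(is.na(x$values))
  cat(nmiss, " missing (below-detection) cells\n", sep = "")
  invisible(x)
}

#' @export
dim.study_dataset <- function(x) dim(x$values)

#' Read a study from abundance and metadata tables
#'
#' The abundance table is wide format: a leading `sample_id` column followed
#' by one column per metabolite; empty cells or `NA` are read as
#' below-detection missing values.  The metadata table has columns
#' `sample_id`, `subject_id`, `cohort`, `week`.  The delimiter is inferred
#' from the file extension (`.tsv`/`.txt` = tab, otherwise comma) and can be
#' overridden with `sep`.
#'
#' @param values_path,meta_path paths to the two tables.
#' @param sep optional field delimiter overriding extension-based detection.
#' @return A validated [study_dataset].
#' @export
read_study <- function(values_path, meta_path, sep = NULL) {
  vals <- read.table(values_path, header = TRUE,
                     sep = sep %||% sep_for(values_path),
                     check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.table(meta_path, header = TRUE,
                     sep = sep %||% sep_for(meta_path),
                     check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(vals))
    stop("invalid metadata: abundance table lacks a sample_id column")
  m <- as.matrix(vals[, setdiff(names(vals), "sample_id"), drop = FALSE])
  rownames(m) <- vals$sample_id
  if (!all(vals$sample_id %in% meta$sample_id) ||
      !all(meta$sample_id %in% vals$sample_id))
    stop("invalid metadata: sample ids of the two tables do not match")
  meta <- meta[match(vals$sample_id, meta$sample_id), , drop = FALSE]
  study_dataset(m, meta)
}

#' Write a study to abundance and metadata tables
#'
#' Inverse of [read_study()]; missing cells are written as `NA`.
#'
#' @param dataset a [study_dataset].
#' @param values_path,meta_path output paths; delimiter follows the
#'   extension as in [read_study()].
#' @return Invisibly, the dataset.
#' @export
write_study <- function(dataset, values_path, meta_path) {
  stopifnot(inherits(dataset, "study_dataset"))
  fmt <- dataset$values
  storage.mode(fmt) <- "character"
  fmt[] <- sprintf("%.17g", dataset$values)   # round-trips doubles exactly
  fmt[is.na(dataset$values)] <- NA_character_
  out <- data.frame(sample_id = dataset$meta$sample_id,
                    fmt, check.names = FALSE)
  write.table(out, values_path, sep = sep_for(values_path),
              row.names = FALSE, quote = FALSE)
  write.table(dataset$meta, meta_path, sep = sep_for(meta_path),
              row.names = FALSE, quote = FALSE)
  invisible(dataset)
}

sep_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select a cohort/week view of a study
#'
#' Returns a lightweight view (no copy of the matrix) of the samples
#' matching the selector.  `"all"` matches every level.  Column order is
#' never changed, so fitted models remain aligned with any view.
#'
#' @param dataset a [study_dataset].
#' @param cohort `"ASD"`, `"TD"` or `"all"`.
#' @param week one of 0, 3, 10, 18 or `"all"`.
#' @return An object of class `cohort_view` with the selected row indices,
#'   per-class counts `n_k` and class count `K`.
#' @export
select_samples <- function(dataset, cohort = "all", week = "all") {
  stopifnot(inherits(dataset, "study_dataset"))
  keep <- rep(TRUE, nrow(dataset$meta))
  if (!identical(cohort, "all")) {
    if (!all(cohort %in% COHORT_LEVELS)) stop("invalid metadata: cohort")
    keep <- keep & dataset$meta$cohort %in% cohort
  }
  if (!identical(week, "all")) {
    week <- as.integer(week)
    if (!all(week %in% WEEK_LEVELS)) stop("invalid metadata: week")
    keep <- keep & dataset$meta$week %in% week
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty cohort")
  n_k <- table(factor(dataset$meta$cohort[idx], levels = COHORT_LEVELS))
  n_k <- n_k[n_k > 0]
  structure(list(dataset = dataset, idx = idx, cohort = cohort,
                 week = week, n_k = c(n_k), K = length(n_k)),
            class = "cohort_view")
}

#' @export
print.cohort_view <- function(x, ...) {
  cat("<cohort_view> ", length(x$idx), " samples (",
      paste(names(x$n_k), x$n_k, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Extract the abundance matrix of a view
#'
#' @param view a `cohort_view` from [select_samples()].
#' @param metabolites optional metabolite ids to keep, in the given order.
#' @return Numeric matrix of the selected samples (and columns).
#' @export
view_values <- function(view, metabolites = NULL) {
  stopifnot(inherits(view, "cohort_view"))
  m <- view$dataset$values[view$idx, , drop = FALSE]
  if (!is.null(metabolites)) {
    missing <- setdiff(metabolites, colnames(m))
    if (length(missing))
      stop("feature misalignment: unknown metabolites ",
           paste(missing, collapse = ", "))
    m <- m[, metabolites, drop = FALSE]
  }
  m
}

#' @rdname view_values
#' @export
view_meta <- function(view) {
  stopifnot(inherits(view, "cohort_view"))
  view$dataset$meta[view$idx, , drop = FALSE]
}

#' Keep a subset of metabolites
#'
#' @param dataset a [study_dataset].
#' @param metabolites character vector of metabolite ids to keep (order is
#'   preserved as given).
#' @return A new [study_dataset] restricted to those columns.
#' @export
keep_metabolites <- function(dataset, metabolites) {
  stopifnot(inherits(dataset, "study_dataset"))
  missing <- setdiff(metabolites, colnames(dataset$values))
  if (length(missing))
    stop("feature misalignment: unknown metabolites ",
         paste(missing, collapse = ", "))
  study_dataset(dataset$values[, metabolites, drop = FALSE], dataset$meta)
}
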