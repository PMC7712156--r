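# Shared machinery for the subset search: everything the per-subset fit
# needs is precomputed once on the week-0 candidate matrix.  The weighted
# within- and between-class scatter of any subset is a submatrix of the
# full-p scatter, so each subset costs one small solve plus a rank pass.
search_context <- function(dataset, candidates, positive = "ASD") {
  w0 <- select_samples(dataset, week = 0L)
  X <- view_values(w0, candidates)
  labels <- view_meta(w0)$cohort
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 < 2L || n2 < 2L) stop("degenerate labels")
  mu_pos <- colMeans(X[pos, , drop = FALSE])
  mu_neg <- colMeans(X[!pos, , drop = FALSE])
  mu <- colMeans(X)
  C1 <- sweep(X[pos, , drop = FALSE], 2, mu_pos)
  C2 <- sweep(X[!pos, , drop = FALSE], 2, mu_neg)
  list(X = X, pos = pos, n1 = n1, n2 = n2,
       d = mu_pos - mu_neg,
       S_W = n1 * crossprod(C1) + n2 * crossprod(C2),
       S_B = n1 * tcrossprod(mu_pos - mu) + n2 * tcrossprod(mu_neg - mu),
       candidates = colnames(X))
}

# Fit one subset inside a search context; returns c(auroc, J).
fit_subset <- function(ctx, s) {
  Sw <- ctx$S_W[s, s, drop = FALSE]
  d <- ctx$d[s]
  W <- tryCatch(solve(Sw, d), error = function(e) {
    ridge <- 1e-8 * sum(diag(Sw)) / length(s)
    solve(Sw + diag(ridge, length(s)), d)
  })
  sc <- ctx$X[, s, drop = FALSE] %*% W
  r <- rank(sc)
  a <- (sum(r[ctx$pos]) - ctx$n1 * (ctx$n1 + 1) / 2) / (ctx$n1 * ctx$n2)
  Sb <- ctx$S_B[s, s, drop = FALSE]
  j <- sum(W * (Sb %*% W)) / sum(W * (Sw %*% W))
  c(max(a, 1 - a), j)
}

#' Exhaustive Fisher-discriminant subset search
#'
#' Fits a two-class Fisher discriminant model to every size-`k` subset of
#' the candidate metabolites on the week-0 samples, scores its empirical
#' (raw-score) AUROC, and returns the `top_n` subsets ranked by AUROC, ties
#' broken by larger separation `J` and then by canonical subset order.  The
#' result is deterministic and independent of the input order of
#' `candidates`.
#'
#' When `choose(length(candidates), k)` exceeds `max_combinations`, that
#' many subsets are drawn uniformly at random with `subsample_seed` instead
#' of full enumeration (a desk-scale guard; the canonical procedure is the
#' full enumeration).
#'
#' @param dataset a preprocessed [study_dataset].
#' @param candidates character vector of screened metabolite ids.
#' @param k subset size (2, 3 or 4).
#' @param top_n number of top models to keep (default 1000).
#' @param max_combinations enumeration cap (default 2e6).
#' @param subsample_seed seed used only beyond the cap.
#' @return A data frame of class `model_records` with columns `metabolites`
#'   (ids joined by `"; "`), `auroc` and `J`, plus a list attribute
#'   `subsets` holding the id vectors.
#' @export
exhaustive_search <- function(dataset, candidates, k, top_n = 1000L,
                              max_combinations = 2e6,
                              subsample_seed = 1L) {
  candidates <- sort(unique(candidates))
  if (k > length(candidates)) stop("not enough candidates")
  ctx <- search_context(dataset, candidates)
  total <- choose(length(candidates), k)
  if (total <= max_combinations) {
    subsets <- combn(length(candidates), k)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(subsample_seed)
    subsets <- replicate(as.integer(max_combinations),
                         sort(sample.int(length(candidates), k)))
    subsets <- subsets[, !duplicated(t(subsets)), drop = FALSE]
    subsets <- subsets[, do.call(order, as.data.frame(t(subsets))),
                       drop = FALSE]
  }
  rank_records(ctx, subsets, top_n)
}

# Fit all subsets (columns of an index matrix, canonically ordered),
# rank by (-auroc, -J, lexicographic) and keep the top_n.
rank_records <- function(ctx, subsets, top_n) {
  m <- ncol(subsets)
  a <- numeric(m); j <- numeric(m)
  for (i in seq_len(m)) {
    fit <- fit_subset(ctx, subsets[, i])
    a[i] <- fit[1L]; j[i] <- fit[2L]
  }
  ord <- order(-a, -j)            # stable: lexicographic among full ties
  keep <- ord[seq_len(min(top_n, m))]
  ids <- lapply(keep, function(i) ctx$candidates[subsets[, i]])
  out <- data.frame(
    metabolites = vapply(ids, paste, character(1), collapse = "; "),
    auroc = a[keep], J = j[keep], stringsAsFactors = FALSE)
  attr(out, "subsets") <- ids
  class(out) <- c("model_records", "data.frame")
  out
}

#' Subsets of a model-records table
#'
#' @param records a `model_records` data frame.
#' @return List of character vectors of metabolite ids.
#' @export
record_subsets <- function(records) attr(records, "subsets")

#' Greedy augmentation of four-metabolite models to five
#'
#' Every top four-metabolite model is extended by each remaining candidate
#' not already in it; duplicate five-subsets arising from different parents
#' are collapsed; each unique five-subset is fitted and the `top_n` are
#' returned with the same ranking rule as [exhaustive_search()].
#'
#' @param top4 a `model_records` table of 4-subsets.
#' @param dataset the preprocessed [study_dataset].
#' @param candidates the full screened candidate id vector.
#' @param top_n number of top five-metabolite models to keep (default
#'   1000).
#' @return A `model_records` data frame of 5-subsets.
#' @export
augment_to_five <- function(top4, dataset, candidates, top_n = 1000L) {
  parents <- record_subsets(top4)
  if (is.null(parents) || length(parents) == 0L)
    stop("nothing to augment")
  candidates <- sort(unique(candidates))
  ctx <- search_context(dataset, candidates)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  fives <- list()
  for (par in parents) {
    pidx <- match(par, candidates)
    if (anyNA(pidx))
      stop("feature misalignment: parent subset outside candidate set")
    for (add in setdiff(seq_along(candidates), pidx)) {
      s <- sort(c(pidx, add))
      key <- paste(s, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      fives[[length(fives) + 1L]] <- s
    }
  }
  subsets <- do.call(cbind, fives)
  subsets <- subsets[, do.call(order, as.data.frame(t(subsets))),
                     drop = FALSE]
  rank_records(ctx, subsets, top_n)
}

#' Frequency of appearance in the top models
#'
#' @param records a `model_records` table.
#' @return Data frame with `metabolite` and `frequency` (fraction of the
#'   recorded models containing it), sorted decreasing.
#' @export
metabolite_frequency <- function(records) {
  ids <- unlist(record_subsets(records))
  tab <- sort(table(ids), decreasing = TRUE) / nrow(records)
  data.frame(metabolite = names(tab), frequency = as.numeric(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Leave-one-out cross-validation of a metabolite panel
#'
#' One fold per week-0 sample: the sample is held out, the Fisher
#' discriminant model is refit on the remaining samples, the kernel density
#' of the training treated-cohort (positive-class) scores is refit, the
#' threshold is placed at each Type II error level `beta`, and the held-out
#' sample is classified as positive when its score is at least the
#' threshold.  Sensitivity (TPR) aggregates over positive folds,
#' specificity (TNR) over negative folds.
#'
#' @param dataset a preprocessed [study_dataset].
#' @param subset character vector of panel metabolite ids.
#' @param betas Type II error levels (default `c(0.01, 0.05, 0.1, 0.2)`).
#' @param positive the treated-cohort label (default `"ASD"`).
#' @return An object of class `cv_report`: `metabolites`, a `performance`
#'   data frame (`beta`, `tpr`, `tnr`, `balanced_accuracy`), and a `folds`
#'   data frame of per-fold held-out scores and predictions.
#' @export
loo_cv <- function(dataset, subset, betas = c(0.01, 0.05, 0.1, 0.2),
                   positive = "ASD") {
  w0 <- select_samples(dataset, week = 0L)
  X <- view_values(w0, subset)
  labels <- view_meta(w0)$cohort
  n <- nrow(X)
  if (length(subset) >= min(table(labels)))
    stop("fold degeneracy: panel size must be below the smaller class")
  preds <- matrix(NA, n, length(betas))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr_labels <- labels[-i]
    if (length(unique(tr_labels)) < 2L || any(table(tr_labels) < 2L))
      stop("fold degeneracy: a class was emptied")
    model <- fit_fda(X[-i, , drop = FALSE], tr_labels, positive = positive)
    tr_scores <- fda_project(model, X[-i, , drop = FALSE])
    dens <- fit_kde(tr_scores[tr_labels == positive])
    s <- fda_project(model, X[i, , drop = FALSE])
    scores[i] <- s
    for (b in seq_along(betas)) {
      t <- threshold_at_beta(dens, betas[b])$threshold
      preds[i, b] <- s >= t
    }
  }
  is_pos <- labels == positive
  perf <- data.frame(
    beta = betas,
    tpr = colMeans(preds[is_pos, , drop = FALSE]),
    tnr = colMeans(!preds[!is_pos, , drop = FALSE]))
  perf$balanced_accuracy <- (perf$tpr + perf$tnr) / 2
  structure(list(metabolites = subset, performance = perf,
                 folds = data.frame(sample_id = view_meta(w0)$sample_id,
                                    label = labels, score = scores,
                                    preds)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> panel: ", paste(x$metabolites, collapse = ", "), "\n",
      sep = "")
  print(x$performance, row.names = FALSE)
  invisible(x)
}

#' Select the best cross-validated panels
#'
#' Returns *all* reports achieving the maximal balanced accuracy
#' `(TPR + TNR) / 2` at the selection `beta`; ties are preserved, since
#' distinct panels can cross-validate identically.
#'
#' @param reports list of `cv_report` objects.
#' @param beta selection Type II error level (default 0.05).
#' @return List of the tied best `cv_report` objects.
#' @export
select_best <- function(reports, beta = 0.05) {
  if (length(reports) == 0L) stop("nothing to select from")
  acc <- vapply(reports, function(r) {
    row <- r$performance[r$performance$beta == beta, ]
    if (nrow(row) == 0L) stop("beta ", beta, " absent from a cv_report")
    row$balanced_accuracy
  }, numeric(1))
  reports[acc == max(acc)]
}
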