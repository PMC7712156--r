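#' Orientation-free AUROC of a single variable
#'
#' Computes the area under the receiver operating characteristic curve by
#' pairwise concordance (ties counted one half), i.e. the Mann-Whitney
#' rank-sum statistic scaled by `n1 * n2`, and returns `max(A, 1 - A)` so
#' that the direction of the cohort difference is irrelevant: 0.5 means no
#' separation, 1.0 perfect separation.
#'
#' @param values numeric vector.
#' @param labels two-class vector (factor or character) of the same length.
#' @return AUROC in `[0.5, 1]`.
#' @examples
#' auroc(c(1, 2, 3, 4), c("TD", "TD", "ASD", "ASD"))   # 1
#' auroc(c(1, 3, 2, 4), c("TD", "TD", "ASD", "ASD"))   # 0.75
#' @export
auroc <- function(values, labels) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  cls <- unique(labels)
  if (length(cls) != 2L)
    stop("degenerate labels: need exactly two non-empty classes")
  pos <- labels == cls[1L]
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(values)
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  max(a, 1 - a)
}

#' Paired pre/post change test with normality routing
#'
#' Tests whether paired measurements changed between two time points.  An
#' Anderson-Darling normality test is applied to each time point; if both
#' are non-significant at `normality_alpha` the paired t-test is used,
#' otherwise the Wilcoxon signed-rank test (exact null for small samples
#' without ties, normal approximation with continuity correction otherwise;
#' zero differences dropped).  The Anderson-Darling statistic needs at
#' least 8 observations, so smaller samples are routed to the rank test.
#'
#' @param week0,week18 paired numeric vectors (same subjects, same order).
#' @param normality_alpha significance level for the normality routing
#'   (default 0.05).
#' @return A list with `p` (two-sided p-value) and `test_used`
#'   (`"paired_t"`, `"wilcoxon"`, or `"degenerate"` when all paired
#'   differences are zero, in which case `p = 1`).  Constant non-zero
#'   differences, for which the t statistic is undefined, are routed to
#'   the rank test.
#' @export
paired_change_test <- function(week0, week18, normality_alpha = 0.05) {
  stopifnot(length(week0) == length(week18))
  keep <- !(is.na(week0) | is.na(week18))
  week0 <- week0[keep]; week18 <- week18[keep]
  n <- length(week0)
  if (n < 4L) stop("insufficient samples: need at least 4 pairs")
  d <- week18 - week0
  if (all(d == 0)) return(list(p = 1.0, test_used = "degenerate"))
  normal_at <- function(x) {
    if (length(x) < 8L || sd(x) == 0) return(FALSE)
    p <- tryCatch(nortest::ad.test(x)$p.value, error = function(e) 0)
    p > normality_alpha
  }
  if (sd(d) > 0 && normal_at(week0) && normal_at(week18)) {
    p <- t.test(week18, week0, paired = TRUE)$p.value
    list(p = p, test_used = "paired_t")
  } else {
    p <- suppressWarnings(
      wilcox.test(week18, week0, paired = TRUE, correct = TRUE)$p.value)
    list(p = p, test_used = "wilcoxon")
  }
}

#' Leave-n-out false discovery proportion of a paired change test
#'
#' A stability-based multiple-testing guard: every subset of `n` subjects
#' is dropped in turn, the paired change test is rerun on the remaining
#' pairs, and the returned value is the proportion of subsets whose test is
#' *not* significant at `alpha`.  0 means the result survives every
#' deletion; 1 means it never reaches significance.
#'
#' All `choose(N, n)` subsets are enumerated when that count is at most
#' `max_subsets`; beyond the cap, `max_subsets` subsets are drawn uniformly
#' with the given `subsample_seed`.
#'
#' @param week0,week18 paired numeric vectors of N subjects.
#' @param n number of subjects to drop (1, 2 or 3).
#' @param alpha significance level (default 0.05).
#' @param max_subsets enumeration cap (default 20000).
#' @param subsample_seed seed used only when subsampling kicks in.
#' @return False discovery proportion in `[0, 1]`.
#' @export
leave_n_out_fdr <- function(week0, week18, n, alpha = 0.05,
                            max_subsets = 20000L, subsample_seed = 1L) {
  stopifnot(length(week0) == length(week18), n %in% 1:3)
  N <- length(week0)
  if (N - n < 4L) stop("insufficient samples: N - n must be >= 4")
  total <- choose(N, n)
  if (total <= max_subsets) {
    drops <- combn(N, n, simplify = FALSE)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(subsample_seed)
    drops <- replicate(max_subsets, sort(sample.int(N, n)), simplify = FALSE)
  }
  not_sig <- vapply(drops, function(drop) {
    res <- paired_change_test(week0[-drop], week18[-drop])
    res$p >= alpha
  }, logical(1))
  mean(not_sig)
}

#' Screen candidate metabolites by week-0 AUROC
#'
#' Computes the orientation-free AUROC of every metabolite for separating
#' the two cohorts at week 0 and returns the metabolites whose AUROC
#' strictly exceeds the threshold, ranked by decreasing AUROC with ties
#' broken by metabolite id for determinism.
#'
#' @param dataset a preprocessed [study_dataset].
#' @param threshold candidate AUROC threshold (default 0.6, strict).
#' @return Data frame with columns `metabolite` and `auroc_week0`, sorted.
#' @export
screen_candidates <- function(dataset, threshold = 0.6) {
  w0 <- select_samples(dataset, week = 0L)
  v <- view_values(w0)
  labels <- view_meta(w0)$cohort
  a <- vapply(seq_len(ncol(v)), function(j) auroc(v[, j], labels),
              numeric(1))
  res <- data.frame(metabolite = colnames(v), auroc_week0 = a,
                    stringsAsFactors = FALSE)
  res <- res[res$auroc_week0 > threshold, , drop = FALSE]
  res <- res[order(-res$auroc_week0, res$metabolite), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full univariate screening table
#'
#' Per candidate metabolite: week-0 and week-18 orientation-free AUROC, the
#' paired pre/post change test on the treated cohort (week 0 vs week 18,
#' paired by subject) with its routing, and the leave-n-out false discovery
#' proportions.
#'
#' @param dataset a preprocessed [study_dataset] containing week-18
#'   treated samples.
#' @param threshold AUROC screening threshold (default 0.6).
#' @param alpha significance level for the change test and FDR (default
#'   0.05).
#' @param fdr_n integer vector of leave-n-out depths (default `1:3`; use
#'   `integer(0)` to skip).
#' @param max_subsets passed to [leave_n_out_fdr()].
#' @return Data frame with columns `rank`, `metabolite`, `auroc_week0`,
#'   `auroc_week18`, `change_p`, `test_used` and one `fdr_n<k>` column per
#'   requested depth.
#' @export
univariate_table <- function(dataset, threshold = 0.6, alpha = 0.05,
                             fdr_n = 1:3, max_subsets = 20000L) {
  cand <- screen_candidates(dataset, threshold)
  if (nrow(cand) == 0L) return(cand)
  asd0 <- select_samples(dataset, cohort = "ASD", week = 0L)
  asd18 <- select_samples(dataset, cohort = "ASD", week = 18L)
  m0 <- view_meta(asd0); m18 <- view_meta(asd18)
  common <- intersect(m0$subject_id, m18$subject_id)
  v0 <- view_values(asd0, cand$metabolite)[match(common, m0$subject_id), ,
                                           drop = FALSE]
  v18 <- view_values(asd18, cand$metabolite)[match(common, m18$subject_id), ,
                                             drop = FALSE]
  # week-18 AUROC: treated week-18 samples against control week-0 samples
  td0 <- view_values(select_samples(dataset, cohort = "TD", week = 0L),
                     cand$metabolite)
  a18 <- change_p <- numeric(nrow(cand))
  test_used <- character(nrow(cand))
  fdrs <- matrix(NA_real_, nrow(cand), length(fdr_n))
  for (i in seq_len(nrow(cand))) {
    a18[i] <- auroc(c(v18[, i], td0[, i]),
                    rep(c("ASD", "TD"), c(nrow(v18), nrow(td0))))
    ct <- paired_change_test(v0[, i], v18[, i])
    change_p[i] <- ct$p
    test_used[i] <- ct$test_used
    for (k in seq_along(fdr_n))
      fdrs[i, k] <- leave_n_out_fdr(v0[, i], v18[, i], fdr_n[k],
                                    alpha = alpha,
                                    max_subsets = max_subsets)
  }
  out <- data.frame(rank = seq_len(nrow(cand)),
                    metabolite = cand$metabolite,
                    auroc_week0 = cand$auroc_week0,
                    auroc_week18 = a18,
                    change_p = change_p,
                    test_used = test_used,
                    stringsAsFactors = FALSE)
  if (length(fdr_n)) {
    colnames(fdrs) <- paste0("fdr_n", fdr_n)
    out <- cbind(out, as.data.frame(fdrs))
  }
  out
}

#' Pearson correlation panel
#'
#' Pearson correlation between each panel metabolite and each comparator
#' over the pooled week-0 samples of both cohorts, with the two-sided
#' t-distributed p-value on n - 2 degrees of freedom.  Only pairs with
#' `p < alpha` are reported; a self-pair reports r = 1 with p = 0;
#' zero-variance metabolites are skipped with a warning.
#'
#' @param dataset a preprocessed [study_dataset].
#' @param panel,comparators character vectors of metabolite ids.
#' @param alpha significance cut-off (default 0.05).
#' @return Data frame with columns `panel`, `comparator`, `r`, `p`.
#' @export
correlation_panel <- function(dataset, panel, comparators, alpha = 0.05) {
  w0 <- select_samples(dataset, week = 0L)
  v <- view_values(w0, unique(c(panel, comparators)))
  out <- list()
  for (pm in panel) {
    x <- v[, pm]
    for (cm in comparators) {
      if (cm == pm) {
        out[[length(out) + 1L]] <- data.frame(
          panel = pm, comparator = cm, r = 1.0, p = 0.0,
          stringsAsFactors = FALSE)
        next
      }
      y <- v[, cm]
      ok <- !(is.na(x) | is.na(y))
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        warning("zero-variance metabolite in pair (", pm, ", ", cm,
                "); skipped")
        next
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      if (ct$p.value < alpha)
        out[[length(out) + 1L]] <- data.frame(
          panel = pm, comparator = cm,
          r = unname(ct$estimate), p = ct$p.value,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(panel = character(), comparator = character(),
                      r = numeric(), p = numeric()))
  do.call(rbind, out)
}
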