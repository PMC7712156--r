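test_that("auroc matches hand-computable cases and rejects degenerate labels", {
  expect_equal(auroc(c(1, 2, 3, 4), c("TD", "TD", "ASD", "ASD")), 1.0)
  expect_equal(auroc(rep(2.5, 6), rep(c("TD", "ASD"), 3)), 0.5)
  # frozen from the concordance oracle: 3 of 4 cross-pairs concordant
  expect_equal(auroc(c(1, 3, 2, 4), c("TD", "TD", "ASD", "ASD")), 0.75)
  expect_error(auroc(1:4, rep("ASD", 4)), "degenerate labels")
})

test_that("auroc equals exhaustive pairwise concordance on random instances", {
  set.seed(101)
  for (i in 1:40) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    pool <- if (i %% 2) rnorm(n1 + n2) else sample(1:5, n1 + n2, TRUE)
    pos <- pool[seq_len(n1)]; neg <- pool[n1 + seq_len(n2)]
    a <- concordance_auroc(pos, neg)
    expect_equal(auroc(c(pos, neg), rep(c("ASD", "TD"), c(n1, n2))),
                 max(a, 1 - a))
  }
})

test_that("auroc is invariant under strictly increasing transforms", {
  set.seed(7)
  x <- rexp(30); lab <- rep(c("ASD", "TD"), 15)
  expect_equal(auroc(x, lab), auroc(log(x), lab))
  expect_equal(auroc(x, lab), auroc(x^3 + 2, lab))
})

test_that("paired change test routes by normality and handles degeneracy", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  expect_equal(paired_change_test(x, x),
               list(p = 1.0, test_used = "degenerate"))

  set.seed(12)
  w0 <- rnorm(18); w18 <- w0 + rnorm(18, mean = 5)
  res <- paired_change_test(w0, w18)
  expect_equal(res$test_used, "paired_t")
  expect_lt(res$p, 0.001)

  set.seed(13)
  h0 <- exp(rnorm(18, sd = 3)); h18 <- exp(rnorm(18, sd = 3)) * 2
  res2 <- paired_change_test(h0, h18)
  expect_equal(res2$test_used, "wilcoxon")
})

test_that("leave-n-out FDR equals explicit enumeration and is 0 under a clean shift", {
  set.seed(22)
  w0 <- rnorm(18)
  expect_equal(leave_n_out_fdr(w0, w0 + 10, n = 1), 0.0)

  w0 <- rnorm(9); w18 <- w0 + rnorm(9, mean = 0.8)
  # explicit single-deletion loop oracle
  oracle <- mean(vapply(1:9, function(i)
    paired_change_test(w0[-i], w18[-i])$p >= 0.05, logical(1)))
  expect_equal(leave_n_out_fdr(w0, w18, n = 1), oracle)

  # all C(6, 2) = 15 subsets enumerated
  w0 <- rnorm(6); w18 <- w0 + rnorm(6, mean = 1)
  drops <- combn(6, 2, simplify = FALSE)
  oracle2 <- mean(vapply(drops, function(dr)
    paired_change_test(w0[-dr], w18[-dr])$p >= 0.05, logical(1)))
  expect_equal(leave_n_out_fdr(w0, w18, n = 2), oracle2)

  expect_error(leave_n_out_fdr(rnorm(5), rnorm(5), n = 2),
               "insufficient samples")
})

test_that("screening recovers strongly planted metabolites and respects the threshold", {
  sp <- small_planted()
  cand <- screen_candidates(sp$prep$dataset, 0.6)
  planted <- intersect(sp$study$truth$effects$metabolite,
                       sp$prep$report$retained)
  expect_true(all(planted %in% cand$metabolite))
  expect_true(all(diff(cand$auroc_week0) <= 0))
  expect_equal(nrow(screen_candidates(sp$prep$dataset, 1.0)), 0L)
})

test_that("correlation panel matches the closed-form t transform and handles self-pairs", {
  sp <- small_planted()
  mets <- colnames(sp$prep$dataset$values)[1:6]
  res <- correlation_panel(sp$prep$dataset, mets[1:2], mets, alpha = 1)
  self <- res[res$panel == mets[1] & res$comparator == mets[1], ]
  expect_equal(self$r, 1.0)
  n <- 38
  tstat <- abs(res$r) * sqrt((n - 2) / (1 - res$r^2))
  expect_equal(res$p[res$r < 1], (2 * pt(-tstat, n - 2))[res$r < 1])

  flat <- sp$prep$dataset
  flat$values[select_samples(flat, week = 0L)$idx, mets[3]] <- 1
  expect_warning(correlation_panel(flat, mets[3], mets[1]), "zero-variance")
})

test_that("univariate table reports both-week AUROCs and change tests per candidate", {
  sp <- small_planted()
  tab <- univariate_table(sp$prep$dataset, threshold = 0.8, fdr_n = 1L)
  expect_true(nrow(tab) >= 5)
  expect_true(all(tab$auroc_week0 >= 0.5 & tab$auroc_week0 <= 1))
  expect_true(all(tab$auroc_week18 >= 0.5 & tab$auroc_week18 <= 1))
  expect_true(all(tab$test_used %in% c("paired_t", "wilcoxon", "degenerate")))
  expect_true(all(tab$fdr_n1 >= 0 & tab$fdr_n1 <= 1))
  expect_equal(tab$rank, seq_len(nrow(tab)))
})
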