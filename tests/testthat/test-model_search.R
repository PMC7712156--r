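test_that("exhaustive search enumerates all subsets and matches a naive oracle", {
  sp <- small_planted()
  d <- sp$prep$dataset
  cand <- screen_candidates(d, 0.6)$metabolite[1:10]
  rec <- exhaustive_search(d, cand, k = 2L, top_n = 1000L)
  expect_equal(nrow(rec), choose(10, 2))

  # naive per-subset oracle: independent fit_fda + auroc per subset
  w0 <- select_samples(d, week = 0L)
  labels <- view_meta(w0)$cohort
  subs <- combn(sort(cand), 2, simplify = FALSE)
  oracle <- data.frame(
    metabolites = vapply(subs, paste, character(1), collapse = "; "),
    auroc = vapply(subs, function(s) {
      m <- fit_fda(view_values(w0, s), labels)
      auroc(fda_project(m, view_values(w0, s)), labels)
    }, numeric(1)))
  merged <- merge(as.data.frame(rec)[, c("metabolites", "auroc")], oracle,
                  by = "metabolites")
  expect_equal(merged$auroc.x, merged$auroc.y, tolerance = 1e-12)
  # identical ranking: oracle sorted the same way
  oracle_rank <- oracle$metabolites[order(-oracle$auroc)]
  same_auroc <- function(a, b) isTRUE(all.equal(a, b, tolerance = 1e-12))
  top <- rec$metabolites[1L]
  expect_true(same_auroc(max(oracle$auroc), rec$auroc[1L]))

  with3 <- exhaustive_search(d, cand[1:3], k = 2L)
  expect_equal(nrow(with3), 3L)
  expect_error(exhaustive_search(d, cand[1:3], k = 4L),
               "not enough candidates")
})

test_that("a perfectly separating planted pair ranks first with AUROC 1", {
  set.seed(300)
  n <- 20
  noise <- matrix(rexp(n * 10), n)
  colnames(noise) <- sprintf("noise%02d", 1:10)
  # two metabolites that only separate jointly and fully
  u <- c(rnorm(10, 2), rnorm(10, -2))
  planted <- cbind(sig1 = exp(u + rnorm(n, sd = 0.05)),
                   sig2 = exp(-u + rnorm(n, sd = 0.05)))
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     subject_id = sprintf("p%02d", 1:n),
                     cohort = rep(c("ASD", "TD"), each = 10), week = 0L)
  d <- study_dataset(cbind(planted, noise), meta)
  rec <- exhaustive_search(d, colnames(d$values), k = 2L, top_n = 5L)
  expect_equal(rec$auroc[1L], 1.0)
  expect_true(all(c("sig1", "sig2") %in% record_subsets(rec)[[1L]]))
})

test_that("search ranking is deterministic and input-order independent", {
  sp <- small_planted()
  cand <- screen_candidates(sp$prep$dataset, 0.6)$metabolite[1:8]
  a <- exhaustive_search(sp$prep$dataset, cand, 3L)
  b <- exhaustive_search(sp$prep$dataset, rev(cand), 3L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(record_subsets(a), record_subsets(b))
})

test_that("best attainable AUROC is non-decreasing in subset size", {
  sp <- small_planted()
  cand <- screen_candidates(sp$prep$dataset, 0.6)$metabolite[1:8]
  best <- vapply(2:4, function(k)
    exhaustive_search(sp$prep$dataset, cand, k, top_n = 1L)$auroc,
    numeric(1))
  expect_true(all(diff(best) >= -1e-12))
})

test_that("augmentation forms each missing candidate exactly once, deduplicated", {
  sp <- small_planted()
  d <- sp$prep$dataset
  cand <- screen_candidates(d, 0.6)$metabolite
  top4 <- exhaustive_search(d, cand, k = 4L, top_n = 3L)
  five <- augment_to_five(top4, d, cand, top_n = 10000L)
  subs <- record_subsets(five)
  expect_true(all(vapply(subs, function(s) length(unique(s)) == 5L,
                         logical(1))))
  expect_false(any(duplicated(vapply(subs, paste, character(1),
                                     collapse = ";"))))
  # a single parent produces |candidates| - 4 children
  one <- augment_to_five(exhaustive_search(d, cand, 4L, top_n = 1L),
                         d, cand, top_n = 10000L)
  expect_equal(nrow(one), length(cand) - 4L)
  empty <- top4[0, ]
  attr(empty, "subsets") <- list()
  expect_error(augment_to_five(empty, d, cand), "nothing to augment")
})

test_that("leave-one-out cross-validation has one fold per sample and nails strong panels", {
  sp <- small_planted()
  d <- sp$prep$dataset
  planted <- intersect(sp$study$truth$effects$metabolite,
                       colnames(d$values))
  cv <- loo_cv(d, planted[1:4])
  expect_equal(nrow(cv$folds), 38L)
  perf <- cv$performance[cv$performance$beta == 0.05, ]
  expect_gt(perf$tpr, 0.85)
  expect_gt(perf$tnr, 0.85)
  expect_true(all(cv$performance$tpr >= 0 & cv$performance$tpr <= 1))
  expect_true(all(cv$performance$tnr >= 0 & cv$performance$tnr <= 1))
})

test_that("tied best cross-validation reports are all preserved", {
  mk <- function(ba, mets) {
    perf <- data.frame(beta = 0.05, tpr = ba, tnr = ba,
                       balanced_accuracy = ba)
    structure(list(metabolites = mets, performance = perf,
                   folds = data.frame()), class = "cv_report")
  }
  reports <- list(mk(0.9, "a"), mk(0.95, "b"), mk(0.95, "c"))
  best <- select_best(reports, 0.05)
  expect_equal(vapply(best, function(r) r$metabolites, character(1)),
               c("b", "c"))
  expect_length(select_best(list(mk(0.8, "a")), 0.05), 1L)
  all_tied <- list(mk(0.9, "a"), mk(0.9, "b"))
  expect_length(select_best(all_tied, 0.05), 2L)
  expect_error(select_best(list()), "nothing to select")
})
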