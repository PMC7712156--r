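make_stats <- function(panel, med = NULL, sdv = NULL) {
  med <- med %||% rep(1, length(panel))
  sdv <- sdv %||% rep(1, length(panel))
  names(med) <- names(sdv) <- panel
  structure(list(metabolite = panel, median = med, sd = sdv,
                 scale = med), class = "reference_stats")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("deviation score sums control-SD-normalized absolute gaps", {
  panel <- paste0("m", 1:5)
  stats <- make_stats(panel, sdv = c(0.5, 1, 2, 1, 1))
  at_median <- matrix(1, 1, 5, dimnames = list(NULL, panel))
  expect_equal(deviation_score(at_median, stats, panel), 0)

  one_sd <- matrix(1 + c(0.5, 1, 2, 1, 1), 1, 5,
                   dimnames = list(NULL, panel))
  expect_equal(deviation_score(one_sd, stats, panel), 5)

  bad <- make_stats(panel, sdv = c(0, 1, 1, 1, 1))
  expect_error(deviation_score(one_sd, bad, panel),
               "degenerate reference spread")
})

test_that("deviation score is invariant under joint rescaling of a metabolite", {
  set.seed(41)
  panel <- c("a", "b")
  X <- matrix(rexp(20), 10, 2, dimnames = list(NULL, panel))
  stats <- make_stats(panel, med = c(2, 3), sdv = c(0.7, 1.3))
  d1 <- deviation_score(X, stats, panel)
  X2 <- X; X2[, "a"] <- X[, "a"] * 10
  stats2 <- make_stats(panel, med = c(20, 3), sdv = c(7, 1.3))
  expect_equal(deviation_score(X2, stats2, panel), d1)
})

test_that("trajectory reproduces beta at week 0 and omits absent weeks", {
  sp <- small_planted()
  d <- sp$prep$dataset
  panel <- intersect(sp$study$truth$effects$metabolite,
                     colnames(d$values))[1:4]
  w0 <- select_samples(d, week = 0L)
  model <- fit_fda(view_values(w0, panel), view_meta(w0)$cohort)
  asd0 <- fda_project(model, view_values(select_samples(d, "ASD", 0L), panel))
  thr <- threshold_at_beta(fit_kde(asd0), 0.05)
  traj <- score_trajectory(model, d, sp$prep$stats, thr)
  expect_equal(traj$type2$type2_error[traj$type2$week == 0L], 0.05,
               tolerance = 1e-3 / 0.05)
  expect_setequal(traj$type2$week, c(0L, 3L, 10L, 18L))
  expect_true(all(traj$type2$type2_error >= 0 &
                    traj$type2$type2_error <= 1))
  # control baseline row present
  expect_true(any(traj$panel_scores$cohort == "TD"))

  # a dataset without late weeks: skipped with a warning
  early <- study_dataset(
    d$values[d$meta$week %in% c(0L, 3L), , drop = FALSE],
    d$meta[d$meta$week %in% c(0L, 3L), , drop = FALSE])
  expect_warning(tr2 <- score_trajectory(model, early, sp$prep$stats, thr),
                 "omitted")
  expect_setequal(tr2$type2$week, c(0L, 3L))
})

test_that("gap-reduction summaries report their formula and a percent", {
  sp <- small_planted()
  d <- sp$prep$dataset
  panel <- intersect(sp$study$truth$effects$metabolite,
                     colnames(d$values))[1:4]
  w0 <- select_samples(d, week = 0L)
  model <- fit_fda(view_values(w0, panel), view_meta(w0)$cohort)
  asd0 <- fda_project(model, view_values(select_samples(d, "ASD", 0L), panel))
  thr <- threshold_at_beta(fit_kde(asd0), 0.05)
  traj <- score_trajectory(model, d, sp$prep$stats, thr)
  for (meth in c("median_of_sums", "sum_of_medians",
                 "mean_abs_median_gap")) {
    red <- panel_gap_reduction(traj, d, sp$prep$stats, method = meth)
    expect_equal(red$method, meth)
    expect_true(is.finite(red$percent_decrease))
    expect_lt(red$percent_decrease, 100)
  }
})

test_that("shift summaries count significance and strict AUROC decreases", {
  res <- data.frame(metabolite = c("a", "b"),
                    auroc_week0 = c(0.8, 0.7),
                    change_p = c(0.01, NA))
  same <- c(a = 0.8, b = 0.7)
  s1 <- shift_summary(res, same)
  expect_equal(s1$pct_lower, 0)
  expect_equal(s1$pct_significant, 50)

  mixed <- c(a = 0.7, b = 0.75)   # one lower, one higher
  expect_equal(shift_summary(res, mixed)$pct_lower, 50)

  with_gaps <- shift_summary(res, mixed,
                             week0_gaps = c(a = 2, b = 2),
                             week18_gaps = c(a = 1, b = 1))
  expect_equal(with_gaps$pct_gap_reduction, 50)

  expect_error(shift_summary(res[0, ], mixed), "nothing to summarize")
})
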