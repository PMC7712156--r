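# Shared in-code fixtures.  Everything is generated at test time; nothing
# binary ships with the package.

# Tiny deterministic two-sample, three-metabolite study.
toy_study <- function() {
  m <- matrix(c(1.5, 2.5, 3.5, 0.5, 4.0, 6.0), nrow = 2,
              dimnames = list(c("s1", "s2"), c("m1", "m2", "m3")))
  meta <- data.frame(sample_id = c("s1", "s2"),
                     subject_id = c("subj1", "subj2"),
                     cohort = c("ASD", "TD"), week = c(0L, 0L),
                     stringsAsFactors = FALSE)
  study_dataset(m, meta)
}

# Week-0-only study with explicit values for one metabolite, padded with a
# second constant-free filler column so validation passes.
week0_study <- function(values, cohorts = NULL) {
  n <- length(values)
  if (is.null(cohorts)) cohorts <- rep(c("ASD", "TD"), length.out = n)
  m <- cbind(met_a = values, met_b = seq_len(n) + 0.5)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  meta <- data.frame(sample_id = rownames(m),
                     subject_id = sprintf("subj%02d", seq_len(n)),
                     cohort = cohorts, week = 0L,
                     stringsAsFactors = FALSE)
  study_dataset(m, meta)
}

# Cached default synthetic study (full size); generated once per test run.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(sim_config(seed = 42L))
    cache
  }
})

# Small preprocessed planted study for search/evaluation tests.
small_planted <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- generate_study(sim_config(n_metabolites = 60,
                                         n_discriminating = 10,
                                         effect_size = 3, seed = 11L))
      cache <<- list(study = study,
                     prep = preprocess_study(study$dataset))
    }
    cache
  }
})

# Directional (orientation-dependent) AUROC oracle by exhaustive pairwise
# concordance counting, ties worth one half.
concordance_auroc <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
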