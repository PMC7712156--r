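#' Discover the best cross-validated metabolite panels
#'
#' The headline model-discovery procedure on week-0 data: screen
#' candidates by AUROC, exhaustively search all 2-, 3- and 4-metabolite
#' subsets, greedily augment the top four-metabolite models to five,
#' cross-validate the leading five-metabolite panels (and the best panel
#' of each smaller size, for reference) with leave-one-out folds and
#' KDE-calibrated thresholds, and return every panel tied for the best
#' balanced accuracy at the selection `beta`.
#'
#' @param dataset a preprocessed [study_dataset].
#' @param threshold AUROC screening threshold (default 0.6, strict).
#' @param k_list exhaustive subset sizes (default `c(2, 3, 4)`).
#' @param top_n models recorded per size (default 1000).
#' @param max_candidates optional cap on the candidate pool (kept in AUROC
#'   rank order) to bound the combinatorial search; `NULL` = no cap.
#' @param cv_top_n number of leading five-metabolite panels to
#'   cross-validate (default 50).
#' @param betas Type II error levels for cross-validation.
#' @param selection_beta level at which the best panel is chosen
#'   (default 0.05).
#' @return A list: `candidates` (screening table), `records` (one
#'   `model_records` table per size, named `k2`..`k5`), `cv_reports`
#'   (cross-validated five-metabolite panels), `reference_cv` (best panel
#'   per smaller size), and `best` (list of tied best `cv_report`s).
#' @export
discover_panel <- function(dataset, threshold = 0.6,
                           k_list = c(2L, 3L, 4L), top_n = 1000L,
                           max_candidates = NULL, cv_top_n = 50L,
                           betas = c(0.01, 0.05, 0.1, 0.2),
                           selection_beta = 0.05) {
  screen <- screen_candidates(dataset, threshold)
  cand <- screen$metabolite
  if (!is.null(max_candidates) && length(cand) > max_candidates)
    cand <- cand[seq_len(max_candidates)]
  records <- list()
  for (k in sort(k_list))
    records[[paste0("k", k)]] <- exhaustive_search(dataset, cand, k, top_n)
  if (4L %in% k_list)
    records$k5 <- augment_to_five(records$k4, dataset, cand, top_n)
  reference_cv <- lapply(records[paste0("k", sort(k_list))], function(r)
    loo_cv(dataset, record_subsets(r)[[1L]], betas))
  cv_reports <- list()
  if (!is.null(records$k5)) {
    subs <- record_subsets(records$k5)
    subs <- subs[seq_len(min(cv_top_n, length(subs)))]
    cv_reports <- lapply(subs, function(s) loo_cv(dataset, s, betas))
  }
  pool <- if (length(cv_reports)) cv_reports else reference_cv
  list(candidates = screen, records = records,
       cv_reports = cv_reports, reference_cv = reference_cv,
       best = select_best(pool, selection_beta))
}

#' Assemble a pipeline configuration
#'
#' @param values_path,meta_path input tables ([read_study()]), or `NULL`
#'   when `simulate` is given.
#' @param simulate optional [sim_config()] (or plain list of its
#'   arguments) to generate the study instead of reading it.
#' @param min_fraction detection-limit retention fraction.
#' @param auroc_threshold candidate screening threshold.
#' @param k_list,top_n,max_candidates,cv_top_n,betas,selection_beta see
#'   [discover_panel()].
#' @param fdr_n leave-n-out depths for the univariate table (use
#'   `integer(0)` to skip the expensive stability screen).
#' @param seed integer master seed for every stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(values_path = NULL, meta_path = NULL,
                            simulate = NULL, min_fraction = 0.4,
                            auroc_threshold = 0.6,
                            k_list = c(2L, 3L, 4L), top_n = 1000L,
                            max_candidates = NULL, cv_top_n = 50L,
                            betas = c(0.01, 0.05, 0.1, 0.2),
                            selection_beta = 0.05, fdr_n = 1L,
                            seed = 1L) {
  if (is.null(simulate) && (is.null(values_path) || is.null(meta_path)))
    stop("invalid metadata/path: provide input tables or a simulation config")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    simulate <- do.call(sim_config, simulate)
  stopifnot(min_fraction > 0, min_fraction < 1,
            auroc_threshold >= 0.5, auroc_threshold <= 1,
            all(betas > 0 & betas < 1), selection_beta %in% betas)
  structure(list(values_path = values_path, meta_path = meta_path,
                 simulate = simulate, min_fraction = min_fraction,
                 auroc_threshold = auroc_threshold,
                 k_list = as.integer(k_list), top_n = as.integer(top_n),
                 max_candidates = max_candidates,
                 cv_top_n = as.integer(cv_top_n), betas = betas,
                 selection_beta = selection_beta,
                 fdr_n = as.integer(fdr_n), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file; keys are the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the study, then runs preprocessing, univariate
#' screening, subset search with augmentation, cross-validation and the
#' longitudinal trajectory evaluation, writing one artifact per stage plus
#' a run manifest to `out_dir`.  Identical config and seed give
#' byte-identical numeric outputs.  On a stage failure, artifacts written
#' so far are retained and a `FAILED` marker names the stage.
#'
#' @param config a [pipeline_config()] (or list of its arguments, or a
#'   path to a YAML/JSON config).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    cat(line, "\n", file = file.path(out_dir, "pipeline.log"),
        append = TRUE, sep = "")
  }
  stage <- "setup"
  tsv <- function(df, name) write.table(
    df, file.path(out_dir, name), sep = "\t", row.names = FALSE,
    quote = FALSE)
  result <- tryCatch({
    set.seed(config$seed)
    stage <- "input"
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- config$seed
      study <- generate_study(sim)
      raw <- study$dataset
      write_simulated_study(study, file.path(out_dir, "simulated_input"))
      logf("input: simulated ", nrow(raw$values), " samples x ",
           ncol(raw$values), " metabolites")
    } else {
      raw <- read_study(config$values_path, config$meta_path)
      logf("input: read ", nrow(raw$values), " samples x ",
           ncol(raw$values), " metabolites")
    }

    stage <- "preprocess"
    prep <- preprocess_study(raw, config$min_fraction)
    tsv(data.frame(metabolite = names(prep$report$above_limit),
                   above_limit = prep$report$above_limit,
                   retained = names(prep$report$above_limit) %in%
                     prep$report$retained),
        "preprocess_report.tsv")
    jsonlite::write_json(
      list(n_retained = length(prep$report$retained),
           n_removed = length(prep$report$removed),
           qualifying_count = prep$report$qualifying_count,
           n_week0 = prep$report$n),
      file.path(out_dir, "preprocess_report.json"), auto_unbox = TRUE)
    logf("preprocess: ", length(prep$report$retained), " retained, ",
         length(prep$report$removed), " removed")

    stage <- "univariate"
    uni <- univariate_table(prep$dataset, config$auroc_threshold,
                            fdr_n = config$fdr_n)
    tsv(uni, "univariate.tsv")
    logf("univariate: ", nrow(uni), " candidates above AUROC ",
         config$auroc_threshold)

    stage <- "search"
    disc <- discover_panel(prep$dataset, config$auroc_threshold,
                           config$k_list, config$top_n,
                           config$max_candidates, config$cv_top_n,
                           config$betas, config$selection_beta)
    for (nm in names(disc$records))
      tsv(as.data.frame(disc$records[[nm]]), paste0("search_", nm, ".tsv"))
    if (!is.null(disc$records$k5))
      tsv(metabolite_frequency(disc$records$k5), "frequency_k5.tsv")
    logf("search: ", length(disc$cv_reports),
         " five-metabolite panels cross-validated")

    stage <- "crossval"
    cv_rows <- do.call(rbind, lapply(disc$best, function(r)
      data.frame(panel = paste(r$metabolites, collapse = "; "),
                 r$performance)))
    tsv(cv_rows, "cv_report.tsv")
    best <- disc$best[[1L]]
    logf("crossval: best panel ", paste(best$metabolites, collapse = ", "))

    stage <- "evaluate"
    w0 <- select_samples(prep$dataset, week = 0L)
    model <- fit_fda(view_values(w0, best$metabolites),
                     view_meta(w0)$cohort)
    asd_scores <- fda_project(
      model, view_values(select_samples(prep$dataset, "ASD", 0L),
                         best$metabolites))
    thr <- threshold_at_beta(fit_kde(asd_scores), config$selection_beta)
    traj <- suppressWarnings(
      score_trajectory(model, prep$dataset, prep$stats, thr))
    tsv(traj$type2, "trajectory_type2.tsv")
    tsv(traj$panel_scores, "trajectory_panel_scores.tsv")
    tsv(traj$metabolite_scores, "trajectory_metabolite_scores.tsv")
    for (nm in names(traj$densities))
      tsv(density_grid(traj$densities[[nm]]),
          paste0("density_", nm, ".tsv"))
    logf("evaluate: type II error by week: ",
         paste(round(traj$type2$type2_error, 3), collapse = ", "))

    stage <- "manifest"
    cfg_json <- jsonlite::toJSON(
      config[!vapply(config, is.null, logical(1))],
      auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(
      list(config = jsonlite::fromJSON(cfg_json),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("fdapanel")),
           r_version = R.version.string),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    list(prep = prep, univariate = uni, discovery = disc,
         trajectory = traj, model = model, threshold = thr)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
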