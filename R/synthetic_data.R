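#' Configuration for the synthetic two-cohort study generator
#'
#' The generator emulates a longitudinal fecal-metabolomics intervention
#' study: a treated cohort (ASD, sampled at weeks 0, 3, 10 and 18) and a
#' control cohort (TD, week 0 only).  Log-abundances follow a
#' block-equicorrelated Gaussian copula and are exponentiated, giving
#' non-negative right-skewed values; a minority of metabolites carry a
#' cohort effect; the lowest week-0 values of each metabolite are censored
#' to mimic a detection limit; and follow-up weeks move each treated
#' subject's log-values toward the control mean according to a
#' responder/non-responder mixture, which makes late-week discriminant
#' scores bimodal.
#'
#' @param n_asd,n_td subjects per cohort (defaults 18 and 20).
#' @param n_metabolites number of measured metabolites (default 669).
#' @param n_discriminating number of metabolites with a planted cohort
#'   effect (default 20); effects are planted half up, half down.
#' @param effect_size standardized log-scale shift per discriminating
#'   metabolite (default 1.5).
#' @param block_size,block_rho size and within-block correlation of the
#'   equicorrelated log-abundance blocks (defaults 5 and 0.3).
#' @param censor_fraction fraction of the lowest week-0 values per
#'   metabolite set missing, mimicking a detection limit (default 0.1;
#'   must be < 0.4).
#' @param responder_fraction probability that a treated subject responds to
#'   the intervention (default 0.7).
#' @param lambda_responder,lambda_nonresponder fraction of the planted
#'   ASD-TD log-mean gap closed at weeks 3, 10 and 18 for responders
#'   (default `c(0.4, 0.7, 0.8)`) and non-responders
#'   (default `c(0, 0.1, 0.1)`); each must be in `[0, 1]` and
#'   non-decreasing.
#' @param subject_rho correlation between a subject's week-0 and follow-up
#'   log-residuals (default 0.5), giving the within-subject dependence that
#'   paired tests rely on.
#' @param week3_dropout number of treated subjects missing at week 3
#'   (default 1).
#' @param seed integer seed; the same config is bit-reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_asd = 18L, n_td = 20L, n_metabolites = 669L,
                       n_discriminating = 20L, effect_size = 1.5,
                       block_size = 5L, block_rho = 0.3,
                       censor_fraction = 0.1, responder_fraction = 0.7,
                       lambda_responder = c(0.4, 0.7, 0.8),
                       lambda_nonresponder = c(0.0, 0.1, 0.1),
                       subject_rho = 0.5, week3_dropout = 1L, seed = 1L) {
  cfg <- list(n_asd = as.integer(n_asd), n_td = as.integer(n_td),
              n_metabolites = as.integer(n_metabolites),
              n_discriminating = as.integer(n_discriminating),
              effect_size = as.numeric(effect_size),
              block_size = as.integer(block_size),
              block_rho = as.numeric(block_rho),
              censor_fraction = as.numeric(censor_fraction),
              responder_fraction = as.numeric(responder_fraction),
              lambda_responder = as.numeric(lambda_responder),
              lambda_nonresponder = as.numeric(lambda_nonresponder),
              subject_rho = as.numeric(subject_rho),
              week3_dropout = as.integer(week3_dropout),
              seed = as.integer(seed))
  ok <- function(cond, what) if (!isTRUE(cond))
    stop("invalid simulation config: ", what)
  ok(cfg$n_asd >= 2 && cfg$n_td >= 2, "need at least 2 subjects per cohort")
  ok(cfg$n_metabolites >= 1, "n_metabolites >= 1")
  ok(cfg$n_discriminating >= 0 &&
       cfg$n_discriminating <= cfg$n_metabolites,
     "n_discriminating must be <= n_metabolites")
  ok(cfg$censor_fraction >= 0 && cfg$censor_fraction < 0.4,
     "censor_fraction must be in [0, 0.4)")
  ok(cfg$block_size >= 1, "block_size >= 1")
  ok(cfg$block_rho >= 0 && cfg$block_rho < 1, "block_rho in [0, 1)")
  ok(cfg$responder_fraction >= 0 && cfg$responder_fraction <= 1,
     "responder_fraction in [0, 1]")
  for (lam in list(cfg$lambda_responder, cfg$lambda_nonresponder)) {
    ok(length(lam) == 3L, "lambda schedules cover weeks 3, 10, 18")
    ok(all(lam >= 0 & lam <= 1), "lambda in [0, 1]")
    ok(!is.unsorted(lam), "lambda non-decreasing in week")
  }
  ok(cfg$subject_rho >= 0 && cfg$subject_rho < 1, "subject_rho in [0, 1)")
  ok(cfg$week3_dropout >= 0 && cfg$week3_dropout < cfg$n_asd,
     "week3_dropout < n_asd")
  ok(length(cfg$seed) == 1L && !is.na(cfg$seed), "seed must be an integer")
  class(cfg) <- "sim_config"
  cfg
}

# Block-equicorrelated standard-normal draws: rows = samples, cols = variables.
# Variables are grouped into consecutive blocks sharing a latent factor.
rblocknorm <- function(n, p, block_size, rho) {
  block <- rep(seq_len(ceiling(p / block_size)), each = block_size)[seq_len(p)]
  nb <- max(block)
  latent <- matrix(rnorm(n * nb), n, nb)
  sqrt(rho) * latent[, block, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
}

#' Generate a synthetic longitudinal two-cohort study
#'
#' Draws a study under the model described in [sim_config()] and returns
#' both the dataset and the planted ground truth, so recovery of the
#' discriminating panel and of the treatment trajectory can be verified.
#'
#' Week-0 log-abundance of metabolite j in sample i is
#' `mu_j + delta_j * I(ASD) + eps_ij` with `eps` block-equicorrelated
#' standard normal and `delta_j = +/- effect_size` on the discriminating
#' set (0 elsewhere).  At follow-up week w a treated subject's mean shifts
#' to `mu_j + (1 - lambda_w) * delta_j`, with `lambda_w` taken from the
#' responder or non-responder schedule; residuals at follow-up correlate
#' with the subject's week-0 residual through `subject_rho`.  Abundances
#' are `exp()` of the log-values; per metabolite the `censor_fraction`
#' lowest week-0 values are set missing.
#'
#' @param config a [sim_config()].
#' @return A list with elements `dataset` (a [study_dataset]) and `truth`
#'   (class `ground_truth`: data frame `effects` of discriminating
#'   metabolite ids with signed log-scale effects, and named logical
#'   `responder` per treated subject).
#' @examples
#' study <- generate_study(sim_config(n_metabolites = 40, seed = 7))
#' dim(study$dataset)
#' head(study$truth$effects)
#' @export
generate_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  p <- config$n_metabolites
  mets <- sprintf("met_%04d", seq_len(p))
  asd_subj <- sprintf("ASD%02d", seq_len(config$n_asd))
  td_subj <- sprintf("TD%02d", seq_len(config$n_td))

  mu <- rnorm(p)
  delta <- numeric(p)
  disc_idx <- if (config$n_discriminating > 0)
    sort(sample.int(p, config$n_discriminating)) else integer(0)
  if (length(disc_idx)) {
    signs <- rep(c(1, -1), length.out = length(disc_idx))
    delta[disc_idx] <- signs * config$effect_size
  }
  responder <- runif(config$n_asd) < config$responder_fraction
  names(responder) <- asd_subj

  n0 <- config$n_asd + config$n_td
  eps0 <- rblocknorm(n0, p, config$block_size, config$block_rho)
  log0 <- matrix(mu, n0, p, byrow = TRUE) + eps0
  log0[seq_len(config$n_asd), ] <-
    log0[seq_len(config$n_asd), ] + matrix(delta, config$n_asd, p, byrow = TRUE)

  rows <- list(exp(log0))
  meta <- list(data.frame(
    sample_id = paste0(c(asd_subj, td_subj), "_w0"),
    subject_id = c(asd_subj, td_subj),
    cohort = rep(c("ASD", "TD"), c(config$n_asd, config$n_td)),
    week = 0L, stringsAsFactors = FALSE))

  weeks <- c(3L, 10L, 18L)
  for (wi in seq_along(weeks)) {
    keep <- seq_len(config$n_asd)
    if (weeks[wi] == 3L && config$week3_dropout > 0)
      keep <- keep[seq_len(config$n_asd - config$week3_dropout)]
    lam <- ifelse(responder[keep], config$lambda_responder[wi],
                  config$lambda_nonresponder[wi])
    fresh <- rblocknorm(length(keep), p, config$block_size, config$block_rho)
    eps_w <- config$subject_rho * eps0[keep, , drop = FALSE] +
      sqrt(1 - config$subject_rho^2) * fresh
    logw <- matrix(mu, length(keep), p, byrow = TRUE) +
      outer(1 - lam, delta) + eps_w
    rows[[length(rows) + 1L]] <- exp(logw)
    meta[[length(meta) + 1L]] <- data.frame(
      sample_id = paste0(asd_subj[keep], "_w", weeks[wi]),
      subject_id = asd_subj[keep], cohort = "ASD", week = weeks[wi],
      stringsAsFactors = FALSE)
  }

  values <- do.call(rbind, rows)
  colnames(values) <- mets
  meta <- do.call(rbind, meta)

  # detection-limit-like censoring: per metabolite, drop the lowest
  # week-0 values (bottom-quantile, not random)
  n_cens <- floor(config$censor_fraction * n0)
  if (n_cens > 0) {
    for (j in seq_len(p)) {
      ord <- order(values[seq_len(n0), j])[seq_len(n_cens)]
      values[ord, j] <- NA_real_
    }
  }

  truth <- structure(list(
    effects = data.frame(metabolite = mets[disc_idx],
                         effect = delta[disc_idx],
                         stringsAsFactors = FALSE),
    responder = responder), class = "ground_truth")
  list(dataset = study_dataset(values, meta), truth = truth)
}

#' Write a simulated study and its ground truth to disk
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, "abundance.tsv")
  mp <- file.path(dir, "metadata.tsv")
  gp <- file.path(dir, "ground_truth.json")
  write_study(study$dataset, vp, mp)
  jsonlite::write_json(list(effects = study$truth$effects,
                            responder = as.list(study$truth$responder)),
                       gp, auto_unbox = TRUE, digits = NA)
  invisible(c(values = vp, meta = mp, truth = gp))
}
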