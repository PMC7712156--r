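#' Reference summary tables from the motivating MTT study
#'
#' Machine-readable copies of the published summary tables of the
#' open-label microbiota-transfer-therapy fecal-metabolomics study whose
#' design the package's defaults emulate:
#' \describe{
#'   \item{`top50`}{the fifty most discriminating fecal metabolites at
#'     baseline: rank, week-0 and week-18 orientation-free AUROC, the
#'     pre/post change-test p-value where one was reported significant,
#'     and the annotated sub-pathway.}
#'   \item{`correlations`}{significant Pearson correlations between the
#'     optimized five-metabolite panel members and the top metabolites;
#'     `p_is_upper_bound` marks entries published as "< 0.001".}
#'   \item{`deviation`}{control-referenced deviation-score summaries
#'     (median, quartiles) per panel metabolite and per optimized model at
#'     each study week, plus the Type II error of each model at the fixed
#'     week-0 threshold, in percent.}
#' }
#'
#' @param which one of `"top50"`, `"correlations"`, `"deviation"`.
#' @return A data frame.
#' @examples
#' t50 <- reference_table("top50")
#' mean(!is.na(t50$change_p)) * 100   # percent with a significant change
#' @export
reference_table <- function(which = c("top50", "correlations",
                                      "deviation")) {
  which <- match.arg(which)
  file <- switch(which,
                 top50 = "mtt_top50_univariate.tsv",
                 correlations = "mtt_panel_correlations.tsv",
                 deviation = "mtt_panel_deviation.tsv")
  path <- system.file("extdata", file, package = "fdapanel",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
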