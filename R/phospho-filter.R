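#' Post-search filter cascade for SILAC phosphopeptides
#'
#' Applies the four conjunctive retention rules used before any quantitative
#' analysis:
#' \enumerate{
#'   \item observed (identified) in both SILAC experiments;
#'   \item not a decoy;
#'   \item at least one fully localized phosphosite;
#'   \item quantified in both replicates for at least one treatment condition.
#' }
#' The rules are conjunctive, so their application order does not change the
#' retained set; input order is preserved.
#'
#' @param records phosphopeptide tibble (see [load_phosphopeptide_table()]).
#' @param experiments character vector of SILAC experiment labels a record
#'   must cover for rule 1. Defaults to all distinct experiment ids present
#'   in `records`.
#' @return the retained subset of `records`, with an attribute
#'   `"filter_counts"` giving the number of records failing each rule
#'   (a record may fail several).
#' @examples
#' tbl <- generate_phospho_table(phospho_spec(n_peptides = 50, seed = 1))
#' nrow(filter_phosphopeptides(tbl$records))
#' @export
filter_phosphopeptides <- function(records, experiments = NULL) {
  if (!nrow(records)) {
    return(structure(records, filter_counts = c(
      both_experiments = 0L, decoy = 0L, localization = 0L, replicates = 0L
    )))
  }
  experiments <- experiments %||%
    sort(unique(unlist(records$experiment_ids, use.names = FALSE)))

  rule_experiments <- vapply(records$experiment_ids, function(e) {
    all(experiments %in% e)
  }, logical(1))
  rule_decoy <- !records$decoy
  rule_localized <- vapply(records$phosphosites, function(ps) {
    nrow(ps) > 0 && any(ps$localized)
  }, logical(1))
  rule_replicates <- rep(FALSE, nrow(records))
  for (cond in .conditions) {
    cols <- ratio_col(cond)
    both <- Reduce(`&`, lapply(cols, function(cl) !is.na(records[[cl]])))
    rule_replicates <- rule_replicates | both
  }

  keep <- rule_experiments & rule_decoy & rule_localized & rule_replicates
  structure(records[keep, ], filter_counts = c(
    both_experiments = sum(!rule_experiments),
    decoy            = sum(!rule_decoy),
    localization     = sum(!rule_localized),
    replicates       = sum(!rule_replicates)
  ))
}
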