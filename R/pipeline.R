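#' Harmonize, score and standardize one weight table against a panel
#'
#' Convenience wrapper chaining the pipeline stages: variant-quality
#' filtering ([filter_variants()]), allele matching ([match_alleles()]),
#' raw scoring ([compute_prs()]) and control standardization
#' ([standardize_scores()]).
#'
#' @param table weight table.
#' @param panel [dosage_panel()].
#' @param cohort cohort `data.frame`.
#' @param group_by standardization grouping (default `"population"`).
#' @param info_min,eff_n_min variant-quality thresholds.
#' @param ambiguous_policy palindromic-variant policy for
#'   [match_alleles()].
#' @return a `score_set`, with the matching table in the `"matched"`
#'   attribute.
#' @export
prs_pipeline <- function(table, panel, cohort, group_by = "population",
                         info_min = 0.4, eff_n_min = 30,
                         ambiguous_policy = "exclude") {
  meta <- filter_variants(panel$variants, info_min = info_min,
                          eff_n_min = eff_n_min)
  kept <- meta[meta$kept, , drop = FALSE]
  matched <- match_alleles(table, kept, ambiguous_policy = ambiguous_policy)
  # panel_index refers to rows of `kept`; remap to the full panel
  ok <- matched$exclude_reason == "none"
  matched$panel_index[ok] <- match(kept$variant_id[matched$panel_index[ok]],
                                   panel$variants$variant_id)
  raw <- compute_prs(panel, matched)
  out <- standardize_scores(raw, cohort, group_by = group_by)
  attr(out, "matched") <- matched
  out
}

#' Matrix of standardized population-specific scores
#'
#' Scores every population-specific weight table of a simulated (or
#' assembled) input set against the panel and returns the individuals x
#' source-populations matrix of control-standardized scores used by the
#' cross-validated combination.
#'
#' @param weight_tables named list of weight tables (a `"meta"` entry, if
#'   present, is skipped).
#' @param panel [dosage_panel()].
#' @param cohort cohort `data.frame`.
#' @param group_by standardization grouping for each population-specific
#'   score (default population and study, the anchoring used before
#'   combination).
#' @return numeric matrix, rownames = individual ids.
#' @export
population_score_matrix <- function(weight_tables, panel, cohort,
                                    group_by = c("population", "study")) {
  srcs <- setdiff(names(weight_tables), "meta")
  cols <- lapply(srcs, function(s) {
    ss <- prs_pipeline(weight_tables[[s]], panel, cohort,
                       group_by = group_by)
    stats::setNames(ss$z_score, ss$id)[cohort$id]
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(cohort$id, srcs)
  out
}
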