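#' Effective sample size at an imputed variant
#'
#' Information content of an imputed variant, `2 * MAF * (1 - MAF) * N *
#' INFO`: the variance of a perfectly observed biallelic genotype scaled by
#' sample size and imputation quality.
#'
#' @param maf minor allele frequency in \[0, 1\] (values above 0.5 are
#'   accepted and folded implicitly by the symmetry of the formula).
#' @param n sample size, >= 0.
#' @param info imputation INFO score in \[0, 1\].
#' @return numeric vector of effective sample sizes.
#' @examples
#' effective_sample_size(0.5, 100, 1.0)  # 50
#' @export
effective_sample_size <- function(maf, n, info) {
  assert_that(all(is.finite(maf)) && all(maf >= 0 & maf <= 1),
              "maf must be in [0, 1]")
  assert_that(all(is.finite(n)) && all(n >= 0), "n must be >= 0")
  assert_that(all(is.finite(info)) && all(info >= 0 & info <= 1),
              "info must be in [0, 1]")
  2 * maf * (1 - maf) * n * info
}

#' Apply imputation-quality filters to variant metadata
#'
#' Variants are kept iff INFO >= `info_min` and the effective sample size
#' (see [effective_sample_size()]) is >= `eff_n_min`. Variants with missing
#' MAF, INFO or N are flagged as `missing_meta`, never silently kept.
#'
#' @param panel_meta `data.frame` with columns `maf`, `info`, `n` (plus any
#'   identifying columns, carried through).
#' @param info_min minimum INFO score (default 0.4).
#' @param eff_n_min minimum effective sample size (default 30).
#' @return the input with added columns `eff_n`, `kept` (logical) and
#'   `exclude_reason` (`"none"`, `"low_info"`, `"low_eff_n"`,
#'   `"missing_meta"`). A variant failing both filters is labelled
#'   `low_info` (checked first).
#' @export
filter_variants <- function(panel_meta, info_min = 0.4, eff_n_min = 30) {
  assert_that(all(c("maf", "info", "n") %in% names(panel_meta)),
              "panel_meta must have columns maf, info, n")
  out <- panel_meta
  missing <- !stats::complete.cases(out[, c("maf", "info", "n")])
  eff_n <- rep(NA_real_, nrow(out))
  ok <- !missing
  eff_n[ok] <- effective_sample_size(out$maf[ok], out$n[ok], out$info[ok])
  reason <- rep("none", nrow(out))
  reason[!missing & out$info < info_min] <- "low_info"
  reason[!missing & out$info >= info_min & eff_n < eff_n_min] <- "low_eff_n"
  reason[missing] <- "missing_meta"
  out$eff_n <- eff_n
  out$exclude_reason <- reason
  out$kept <- reason == "none"
  out
}

#' Re-map weight-table coordinates across builds with strand complementation
#'
#' Applies a pre-computed coordinate mapping (e.g., from a genome-build
#' liftover) to a weight table. Where the mapping marks a variant as having
#' moved to the reverse strand ('-'), both alleles are replaced by their
#' Watson-Crick complements; weights are never altered. Variants absent
#' from the mapping are dropped with a warning stating how many.
#'
#' @param table weight table `data.frame` with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `effect_weight`.
#' @param mapping `data.frame` with columns `old_chrom`, `old_pos`,
#'   `new_chrom`, `new_pos`, `strand` ('+' or '-').
#' @return the weight table on the new coordinates.
#' @export
apply_strand_mapping <- function(table, mapping) {
  need <- c("old_chrom", "old_pos", "new_chrom", "new_pos", "strand")
  assert_that(all(need %in% names(mapping)),
              "mapping must have columns %s", paste(need, collapse = ", "))
  assert_that(all(mapping$strand %in% c("+", "-")),
              "mapping strand must be '+' or '-'")
  key_t <- paste(table$chrom, table$pos)
  key_m <- paste(mapping$old_chrom, mapping$old_pos)
  idx <- match(key_t, key_m)
  n_drop <- sum(is.na(idx))
  if (n_drop > 0) {
    warning(sprintf("%d variant(s) absent from mapping were dropped", n_drop),
            call. = FALSE)
  }
  keep <- !is.na(idx)
  out <- table[keep, , drop = FALSE]
  idx <- idx[keep]
  out$chrom <- as.character(mapping$new_chrom[idx])
  out$pos <- mapping$new_pos[idx]
  minus <- mapping$strand[idx] == "-"
  if (any(minus)) {
    out$effect_allele[minus] <- complement_allele(out$effect_allele[minus])
    out$other_allele[minus] <- complement_allele(out$other_allele[minus])
  }
  rownames(out) <- NULL
  out
}

#' Match weight-table alleles against a dosage panel
#'
#' Joins a weight table to panel variant metadata on (chrom, pos) and
#' determines, for each variant, how the effect allele relates to the
#' panel's alt allele:
#' \describe{
#'   \item{direct}{effect = alt, other = ref: effect dosage is the alt dosage.}
#'   \item{swap}{effect = ref, other = alt: effect dosage is 2 - alt dosage.}
#'   \item{flip}{direct after complementing both weight-table alleles
#'     (opposite strand).}
#'   \item{swap_flip}{swap after complementation.}
#' }
#' Palindromic pairs (A/T, C/G) cannot be strand-resolved and are excluded
#' under the default policy. Both sides must use 1-based coordinates.
#'
#' @param table weight table (`effect_allele`, `other_allele` in A/C/G/T,
#'   `effect_allele != other_allele`, unique (chrom, pos, alleles) rows).
#' @param panel_variants `data.frame` with columns `chrom`, `pos`,
#'   `ref_allele`, `alt_allele` (one row per panel variant).
#' @param ambiguous_policy `"exclude"` (default) drops palindromic variants;
#'   `"assume-plus-strand"` matches them without considering strand flips.
#' @return `data.frame`: weight-table columns plus `panel_index`,
#'   `ref_allele`, `alt_allele`, `orientation` (`direct`/`swap`/`flip`/
#'   `swap_flip`, `NA` when excluded) and `exclude_reason` (`none`,
#'   `ambiguous`, `unmatched`).
#' @export
match_alleles <- function(table, panel_variants,
                          ambiguous_policy = c("exclude", "assume-plus-strand")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  validate_weight_table(table)
  assert_that(all(c("chrom", "pos", "ref_allele", "alt_allele") %in%
                    names(panel_variants)),
              "panel_variants must have chrom, pos, ref_allele, alt_allele")
  key_p <- paste(panel_variants$chrom, panel_variants$pos)
  dup <- duplicated(key_p)
  if (any(dup)) {
    conf <- key_p[dup]
    stop_input("duplicate panel position(s) with conflicting alleles: %s",
               paste(utils::head(conf, 3), collapse = "; "))
  }
  idx <- match(paste(table$chrom, table$pos), key_p)

  out <- table
  out$panel_index <- idx
  out$ref_allele <- panel_variants$ref_allele[idx]
  out$alt_allele <- panel_variants$alt_allele[idx]
  orientation <- rep(NA_character_, nrow(out))
  reason <- rep("none", nrow(out))
  reason[is.na(idx)] <- "unmatched"

  pal <- !is.na(idx) & is_palindromic(out$effect_allele, out$other_allele)
  has <- !is.na(idx)
  eff <- out$effect_allele; oth <- out$other_allele
  ref <- out$ref_allele; alt <- out$alt_allele
  ceff <- complement_allele(eff)
  coth <- complement_allele(oth)

  direct <- has & eff == alt & oth == ref
  swap <- has & eff == ref & oth == alt
  flip <- has & !pal & ceff == alt & coth == ref
  swap_flip <- has & !pal & ceff == ref & coth == alt

  orientation[swap_flip] <- "swap_flip"
  orientation[flip] <- "flip"
  orientation[swap] <- "swap"
  orientation[direct] <- "direct"

  if (ambiguous_policy == "exclude" && any(pal)) {
    orientation[pal] <- NA_character_
    reason[pal] <- "ambiguous"
  }
  reason[has & is.na(orientation) & reason == "none"] <- "unmatched"
  out$orientation <- orientation
  out$exclude_reason <- reason
  rownames(out) <- NULL
  out
}

validate_weight_table <- function(table) {
  need <- c("chrom", "pos", "effect_allele", "other_allele", "effect_weight")
  assert_that(all(need %in% names(table)),
              "weight table must have columns %s", paste(need, collapse = ", "))
  bad <- !(table$effect_allele %in% VALID_ALLELES &
             table$other_allele %in% VALID_ALLELES)
  if (any(bad)) stop_input("allele outside {A,C,G,T} in weight table")
  assert_that(all(table$effect_allele != table$other_allele),
              "effect_allele must differ from other_allele")
  assert_that(all(is.finite(table$effect_weight)), "weights must be finite")
  key <- paste(table$chrom, table$pos, table$effect_allele, table$other_allele)
  assert_that(!anyDuplicated(key),
              "duplicate (chrom, pos, alleles) rows in weight table")
  invisible(TRUE)
}
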