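#' Load the bundled synthetic phecode map
#'
#' A small synthetic ICD-to-phecode map covering all 17 disease categories,
#' shipped for tests and examples. Real phecode maps (same column layout:
#' `icd_code`, `vocabulary`, `phecode`, `phenotype`, `category`, optional
#' `exclusion_low`/`exclusion_high`) can be read with [read_phecode_map()]
#' and used as drop-in replacements.
#'
#' @return `data.frame` phecode map.
#' @export
synthetic_phecode_map <- function() {
  path <- system.file("extdata", "phecode_map_synthetic.csv",
                      package = "t2dprs")
  read_phecode_map(path)
}

#' Read a phecode map CSV
#'
#' @param path CSV with columns `icd_code`, `vocabulary`, `phecode`,
#'   `phenotype`, `category` and optional `exclusion_low`/`exclusion_high`.
#' @return `data.frame` with `phecode` as character.
#' @export
read_phecode_map <- function(path) {
  map <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  need <- c("icd_code", "vocabulary", "phecode", "phenotype", "category")
  assert_that(all(need %in% names(map)),
              "phecode map must have columns %s", paste(need, collapse = ", "))
  for (col in c("exclusion_low", "exclusion_high")) {
    if (col %in% names(map)) map[[col]] <- as.numeric(map[[col]])
  }
  map
}

#' Map ICD records to per-person phecode counts
#'
#' Each record is matched on (code, vocabulary); the count of a phecode for
#' a person is the number of their records mapping to it (a record may map
#' to several phecodes). Records whose code is absent from the map are
#' tallied, not fatal; an unknown vocabulary label is an error.
#'
#' @param records `data.frame` with columns `person_id`, `code`,
#'   `vocabulary`.
#' @param map phecode map (see [read_phecode_map()]).
#' @return list with `counts` (`data.frame`: `person_id`, `phecode`,
#'   `count`) and `n_unmapped` (records not matching any map row).
#' @export
map_icd_to_phecodes <- function(records, map) {
  assert_that(all(c("person_id", "code", "vocabulary") %in% names(records)),
              "records must have person_id, code, vocabulary")
  known_vocab <- unique(map$vocabulary)
  bad <- setdiff(unique(records$vocabulary), known_vocab)
  if (length(bad)) {
    stop_input("unknown vocabulary label(s): %s", paste(bad, collapse = ", "))
  }
  key_r <- paste(records$code, records$vocabulary)
  key_m <- paste(map$icd_code, map$vocabulary)
  hits <- key_r %in% key_m
  n_unmapped <- sum(!hits)
  if (!any(hits)) {
    return(list(counts = data.frame(person_id = character(0),
                                    phecode = character(0),
                                    count = integer(0)),
                n_unmapped = n_unmapped))
  }
  rec <- records[hits, , drop = FALSE]
  # a single ICD code may map to more than one phecode
  map_idx <- split(seq_len(nrow(map)), key_m)
  expand <- map_idx[paste(rec$code, rec$vocabulary)]
  times <- lengths(expand)
  person <- rep(rec$person_id, times)
  phe <- map$phecode[unlist(expand, use.names = FALSE)]
  agg <- stats::aggregate(list(count = rep(1L, length(person))),
                          by = list(person_id = person, phecode = phe), sum)
  list(counts = agg[order(agg$person_id, agg$phecode), ],
       n_unmapped = n_unmapped)
}

#' Define the phenome: per-person case/control/excluded status per phecode
#'
#' A person is a case for a phecode iff their code count is at least
#' `min_code_count` (default 2). Under the default policy a count of
#' exactly 1 is excluded - not a case, and too suggestive to be a clean
#' control. Persons with count 0 are controls unless they are a case for
#' another phecode whose exclusion range covers this phecode (only when the
#' map carries `exclusion_low`/`exclusion_high`).
#'
#' @param counts `counts` `data.frame` from [map_icd_to_phecodes()].
#' @param person_ids character vector of all cohort individuals (persons
#'   with no records are controls everywhere).
#' @param phecodes phecodes to define; default all in `counts`.
#' @param min_code_count minimum count for a valid case (default 2).
#' @param count_one_as_control if `TRUE`, count-1 individuals become
#'   controls instead of being excluded.
#' @param map optional phecode map providing exclusion ranges.
#' @return `data.frame` with columns `person_id`, `phecode`, `status`
#'   (`case`/`control`/`excluded`).
#' @export
define_phenome <- function(counts, person_ids, phecodes = NULL,
                           min_code_count = 2, count_one_as_control = FALSE,
                           map = NULL) {
  assert_that(all(counts$count >= 0), "counts must be >= 0")
  assert_that(min_code_count >= 1, "min_code_count must be >= 1")
  if (is.null(phecodes)) phecodes <- sort(unique(counts$phecode))
  n <- length(person_ids)
  out <- vector("list", length(phecodes))

  use_excl <- !is.null(map) &&
    all(c("exclusion_low", "exclusion_high") %in% names(map))
  phe_num <- suppressWarnings(as.numeric(phecodes))

  # counts matrix persons x phecodes (sparse in spirit, small in practice)
  cnt <- matrix(0L, n, length(phecodes),
                dimnames = list(person_ids, phecodes))
  keep <- counts$phecode %in% phecodes & counts$person_id %in% person_ids
  cc <- counts[keep, , drop = FALSE]
  cnt[cbind(match(cc$person_id, person_ids),
            match(cc$phecode, phecodes))] <- cc$count

  is_case_mat <- cnt >= min_code_count
  for (j in seq_along(phecodes)) {
    status <- rep("control", n)
    status[cnt[, j] >= 1 & cnt[, j] < min_code_count] <-
      if (count_one_as_control) "control" else "excluded"
    status[is_case_mat[, j]] <- "case"
    if (use_excl && !is.na(phe_num[j])) {
      # controls falling in the exclusion range of a phecode they have
      excl_rows <- map[!is.na(map$exclusion_low) &
                         map$exclusion_low <= phe_num[j] &
                         map$exclusion_high >= phe_num[j] &
                         map$phecode != phecodes[j], , drop = FALSE]
      if (nrow(excl_rows)) {
        other <- intersect(unique(excl_rows$phecode), phecodes)
        if (length(other)) {
          has_other <- rowSums(is_case_mat[, other, drop = FALSE]) > 0
          status[status == "control" & has_other] <- "excluded"
        }
      }
    }
    out[[j]] <- data.frame(person_id = person_ids, phecode = phecodes[j],
                           status = status, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Phenome-wide association scan of a PRS
#'
#' One logistic regression per phecode of case/control status on the
#' standardized PRS plus covariates. Phecodes with fewer than `min_cases`
#' cases are skipped (and listed), never emitted. Non-converged or
#' separated fits are flagged in the output.
#'
#' @param scores `score_set` from [standardize_scores()].
#' @param phenome output of [define_phenome()].
#' @param cohort cohort `data.frame` (covariate source), keyed by `id`.
#' @param covariates covariate column names (default age, sex, BMI, 10 PCs).
#' @param min_cases minimum number of phecode cases (default 10).
#' @param map optional phecode map used to annotate phenotype/category.
#' @param population,study labels stored on each result row.
#' @return list with `results` (one [effect_estimate()] row per tested
#'   phecode, plus `phecode`, `phenotype`, `category` columns) and
#'   `skipped` (`data.frame` of phecodes below `min_cases`).
#' @export
run_phewas <- function(scores, phenome, cohort,
                       covariates = c("age", "sex", "bmi",
                                      sprintf("PC%d", 1:10)),
                       min_cases = 10, map = NULL,
                       population = NA_character_, study = NA_character_) {
  assert_that(length(intersect(scores$id, phenome$person_id)) > 0,
              "phenome and scores share no individuals")
  z <- stats::setNames(scores$z_score, scores$id)
  covs <- cohort[match(names(z), cohort$id), covariates, drop = FALSE]
  phecodes <- unique(phenome$phecode)
  res <- list(); skipped <- list()
  for (phe in phecodes) {
    ph <- phenome[phenome$phecode == phe, , drop = FALSE]
    st <- stats::setNames(ph$status, ph$person_id)[names(z)]
    use <- !is.na(st) & st != "excluded"
    y <- as.integer(st[use] == "case")
    n_cases <- sum(y); n_controls <- sum(1 - y)
    if (n_cases < min_cases) {
      skipped[[phe]] <- data.frame(phecode = phe, n_cases = n_cases,
                                   reason = "below min_cases")
      next
    }
    dat <- data.frame(y = y, z = z[use], covs[use, , drop = FALSE])
    fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                      model = FALSE, y = FALSE)
    est <- coef_estimate(fit, "z", label = phe, n_cases = n_cases,
                         n_controls = n_controls, population = population,
                         study = study)
    est$phecode <- phe
    res[[phe]] <- est
  }
  results <- if (length(res)) do.call(rbind, res) else NULL
  if (!is.null(results)) {
    rownames(results) <- NULL
    if (!is.null(map)) {
      i <- match(results$phecode, map$phecode)
      results$phenotype <- map$phenotype[i]
      results$category <- map$category[i]
    }
  }
  list(results = results,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(phecode = character(0), n_cases = integer(0),
                    reason = character(0)))
}

#' Bonferroni significance threshold
#'
#' @param n_phenotypes number of phenotypes tested (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / n_phenotypes`.
#' @examples
#' bonferroni_threshold(20)    # 2.5e-3
#' bonferroni_threshold(1815)  # 2.75e-5 to 3 significant figures
#' @export
bonferroni_threshold <- function(n_phenotypes, alpha = 0.05) {
  assert_that(length(n_phenotypes) == 1 && n_phenotypes >= 1,
              "n_phenotypes must be >= 1")
  alpha / n_phenotypes
}

#' Percentage of significant results, to one decimal
#'
#' Reporting arithmetic used by [summarize_phewas()]:
#' `round(100 * n_significant / n_tested, 1)`.
#'
#' @param n_significant,n_tested counts with `0 <= n_significant <=
#'   n_tested` and `n_tested >= 1`.
#' @return percentage rounded to one decimal.
#' @examples
#' percent_significant(732, 1815)  # 40.3
#' @export
percent_significant <- function(n_significant, n_tested) {
  assert_that(all(n_tested >= 1), "n_tested must be >= 1")
  assert_that(all(n_significant >= 0 & n_significant <= n_tested),
              "n_significant must be in [0, n_tested]")
  round(100 * n_significant / n_tested, 1)
}

#' Summarize PheWAS results across populations
#'
#' Computes, per population: phecodes tested, significant count at that
#' population's Bonferroni threshold, and the percentage (one decimal);
#' per-category shares of the significant hits; pairwise Pearson
#' correlations of log-ORs across phecodes tested in both populations; and
#' overlap counts of the significant sets.
#'
#' @param results_by_population named list of PheWAS `results` data.frames
#'   (one per population).
#' @param alpha family-wise alpha for the per-population Bonferroni
#'   threshold (default 0.05).
#' @return list with `per_population`, `category_shares`, `correlations`,
#'   `overlap`.
#' @export
summarize_phewas <- function(results_by_population, alpha = 0.05) {
  assert_that(length(results_by_population) > 0 &&
                all(vapply(results_by_population, NROW, 1L) > 0),
              "empty PheWAS result set")
  pops <- names(results_by_population)
  per_pop <- do.call(rbind, lapply(pops, function(p) {
    r <- results_by_population[[p]]
    thr <- bonferroni_threshold(nrow(r), alpha)
    n_sig <- sum(r$p < thr, na.rm = TRUE)
    data.frame(population = p, n_tested = nrow(r), n_significant = n_sig,
               percent_significant = percent_significant(n_sig, nrow(r)),
               threshold = thr, stringsAsFactors = FALSE)
  }))
  category_shares <- lapply(stats::setNames(pops, pops), function(p) {
    r <- results_by_population[[p]]
    if (!"category" %in% names(r)) return(NULL)
    thr <- bonferroni_threshold(nrow(r), alpha)
    sig <- r[r$p < thr, , drop = FALSE]
    if (!nrow(sig)) return(NULL)
    tab <- sort(table(sig$category), decreasing = TRUE)
    data.frame(category = names(tab), n = as.integer(tab),
               percent = percent_significant(as.integer(tab), nrow(sig)),
               stringsAsFactors = FALSE)
  })
  correlations <- NULL; overlap <- NULL
  if (length(pops) > 1) {
    pairs <- utils::combn(pops, 2)
    correlations <- data.frame(pop1 = pairs[1, ], pop2 = pairs[2, ],
                               n_shared = NA_integer_, r = NA_real_)
    overlap <- data.frame(pop1 = pairs[1, ], pop2 = pairs[2, ],
                          n_sig_both = NA_integer_)
    for (k in seq_len(ncol(pairs))) {
      r1 <- results_by_population[[pairs[1, k]]]
      r2 <- results_by_population[[pairs[2, k]]]
      shared <- intersect(r1$phecode, r2$phecode)
      correlations$n_shared[k] <- length(shared)
      if (length(shared) >= 3) {
        correlations$r[k] <- stats::cor(
          r1$beta[match(shared, r1$phecode)],
          r2$beta[match(shared, r2$phecode)]
        )
      }
      t1 <- bonferroni_threshold(nrow(r1), alpha)
      t2 <- bonferroni_threshold(nrow(r2), alpha)
      s1 <- r1$phecode[r1$p < t1]; s2 <- r2$phecode[r2$p < t2]
      overlap$n_sig_both[k] <- length(intersect(s1, s2))
    }
  }
  list(per_population = per_pop, category_shares = category_shares,
       correlations = correlations, overlap = overlap)
}
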