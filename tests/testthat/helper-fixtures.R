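# Shared in-code fixtures: a tiny hand-constructed panel and weight table,
# a fast low-dimensional simulation config, and a direct score_set builder.

tiny_panel <- function() {
  dos <- matrix(c(2, 1, 0,
                  1, 2, 0,
                  0, 1, 2,
                  2, 0, 1),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), paste0("v", 1:3)))
  variants <- data.frame(
    variant_id = paste0("v", 1:3), chrom = "1", pos = c(100L, 200L, 300L),
    ref_allele = c("G", "T", "C"), alt_allele = c("A", "C", "A"),
    maf = c(0.3, 0.4, 0.2), info = c(0.95, 0.9, 0.99), n = 4,
    stringsAsFactors = FALSE
  )
  dosage_panel(dos, variants)
}

tiny_weight_table <- function() {
  data.frame(
    variant_id = paste0("v", 1:3), chrom = "1", pos = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "A"), other_allele = c("G", "T", "C"),
    effect_weight = c(0.5, -0.2, 0.1), source_population = "meta",
    stringsAsFactors = FALSE
  )
}

# small, fast simulation: 2 populations, few variants, no interactions
quick_config <- function(n = 500, seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    populations = c("AFR", "EUR"), n_per_population = n, n_variants = 20,
    context_effects = NULL, trait_effects = NULL,
    phenome_spec = data.frame(phecode = "250.2", log_or = log(2),
                              prevalence = 0.1),
    n_studies = 1, seed = seed
  )
  do.call(sim_config, c(args, defaults[setdiff(names(defaults), names(args))]))
}

# score_set built directly from a z-like raw score and statuses
make_score_set <- function(z, status, population = "EUR", study = "S1",
                           ids = NULL) {
  n <- length(z)
  ids <- ids %||% sprintf("i%04d", seq_len(n))
  cohort <- data.frame(id = ids, population = population, study = study,
                       status = status, stringsAsFactors = FALSE)
  standardize_scores(stats::setNames(z, ids), cohort)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
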