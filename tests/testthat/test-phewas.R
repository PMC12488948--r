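toy_map <- function() {
  data.frame(icd_code = c("X1", "X2", "Y1"),
             vocabulary = c("ICD10CM", "ICD10CM", "ICD9CM"),
             phecode = c("P1", "P2", "P1"),
             phenotype = c("one", "two", "one"),
             category = c("catA", "catB", "catA"),
             stringsAsFactors = FALSE)
}

test_that("ICD records aggregate to per-person phecode counts", {
  rec <- data.frame(person_id = c("a", "a", "b", "b", "c"),
                    code = c("X1", "X1", "X1", "ZZZ", "Y1"),
                    vocabulary = "ICD10CM")
  rec$vocabulary[5] <- "ICD9CM"
  out <- map_icd_to_phecodes(rec, toy_map())
  cnt <- out$counts
  expect_equal(cnt$count[cnt$person_id == "a" & cnt$phecode == "P1"], 2L)
  expect_equal(cnt$count[cnt$person_id == "b" & cnt$phecode == "P1"], 1L)
  expect_equal(cnt$count[cnt$person_id == "c" & cnt$phecode == "P1"], 1L)
  expect_equal(out$n_unmapped, 1L)
  rec_bad <- data.frame(person_id = "a", code = "X1", vocabulary = "SNOMED")
  expect_error(map_icd_to_phecodes(rec_bad, toy_map()), "vocabulary")
})

test_that("phenome definition follows the minimum-count rule", {
  counts <- data.frame(person_id = c("a", "b", "d"),
                       phecode = "P1", count = c(2L, 1L, 3L))
  ph <- define_phenome(counts, person_ids = c("a", "b", "c", "d"))
  st <- setNames(ph$status, ph$person_id)
  expect_equal(unname(st[c("a", "b", "c", "d")]),
               c("case", "excluded", "control", "case"))
  # optional policy: count-1 individuals become controls
  ph2 <- define_phenome(counts, person_ids = c("a", "b", "c", "d"),
                        count_one_as_control = TRUE)
  st2 <- setNames(ph2$status, ph2$person_id)
  expect_equal(unname(st2["b"]), "control")
})

test_that("phenome statuses partition the cohort for every phecode", {
  sim <- simulate_cohort(quick_config(
    n = 300, seed = 111,
    phenome_spec = data.frame(phecode = c("250.2", "401.1", "008"),
                              log_or = c(log(2), 0, 0),
                              prevalence = c(0.2, 0.1, 0.05))))
  counts <- map_icd_to_phecodes(sim$icd, sim$phecode_map)$counts
  ph <- define_phenome(counts, person_ids = sim$cohort$id)
  for (phe in unique(ph$phecode)) {
    sub <- ph[ph$phecode == phe, ]
    expect_equal(nrow(sub), nrow(sim$cohort))
    expect_true(all(sub$status %in% c("case", "control", "excluded")))
    expect_equal(sum(sub$status == "case") + sum(sub$status == "control") +
                   sum(sub$status == "excluded"), nrow(sim$cohort))
  }
  # count-1 individuals exist and are excluded under the default policy
  ones <- counts[counts$count == 1, ]
  expect_gt(nrow(ones), 0)
  key <- paste(ph$person_id, ph$phecode)
  expect_true(all(ph$status[match(paste(ones$person_id, ones$phecode),
                                  key)] == "excluded"))
})

test_that("exclusion ranges remove related controls when the map has them", {
  map <- data.frame(icd_code = c("X1", "X2"), vocabulary = "ICD10CM",
                    phecode = c("250.1", "250.2"),
                    phenotype = c("p1", "p2"), category = "catA",
                    exclusion_low = c(250, 250), exclusion_high = c(251, 251))
  counts <- data.frame(person_id = c("a", "a", "b"),
                       phecode = c("250.1", "250.2", "250.2"),
                       count = c(2L, 0L, 2L))
  ph <- define_phenome(counts, person_ids = c("a", "b", "c"),
                       phecodes = c("250.1", "250.2"), map = map)
  st <- ph[ph$phecode == "250.2", ]
  # 'a' is a 250.1 case and count-0 for 250.2: excluded, not control
  expect_equal(st$status[st$person_id == "a"], "excluded")
  expect_equal(st$status[st$person_id == "c"], "control")
})

test_that("phecodes with fewer than 10 cases are skipped, never emitted", {
  set.seed(113)
  n <- 400
  ids <- sprintf("i%04d", 1:n)
  ss <- make_score_set(rnorm(n), rep("control", n), ids = ids)
  cohort <- data.frame(id = ids, population = "EUR", study = "S1",
                       status = "control", age = runif(n, 40, 80),
                       sex = rbinom(n, 1, 0.5))
  ph <- rbind(
    data.frame(person_id = ids, phecode = "rare",
               status = c(rep("case", 9), rep("control", n - 9))),
    data.frame(person_id = ids, phecode = "common",
               status = c(rep("case", 50), rep("control", n - 50)))
  )
  out <- run_phewas(ss, ph, cohort, covariates = c("age", "sex"))
  expect_false("rare" %in% out$results$phecode)
  expect_true("common" %in% out$results$phecode)
  expect_equal(out$skipped$phecode, "rare")
  expect_equal(out$skipped$n_cases, 9L)
})

test_that("a simulated phecode effect is recovered within its CI", {
  sim <- simulate_cohort(sim_config(
    populations = c("AFR", "EUR"), n_per_population = 10000,
    n_variants = 30, context_effects = NULL, trait_effects = NULL,
    phenome_spec = data.frame(phecode = "401.1", log_or = log(1.5),
                              prevalence = 0.05),
    n_studies = 1, seed = 115))
  ss <- prs_pipeline(sim$weight_tables$meta, sim$panel, sim$cohort)
  counts <- map_icd_to_phecodes(sim$icd, sim$phecode_map)$counts
  ph <- define_phenome(counts, person_ids = sim$cohort$id)
  out <- run_phewas(ss, ph, sim$cohort, map = sim$phecode_map,
                    covariates = c("age", "sex", "bmi"))
  r <- out$results[out$results$phecode == "401.1", ]
  expect_true(r$ci_low <= 1.5 && 1.5 <= r$ci_high)
  expect_equal(r$category, "circulatory system")
})

test_that("Bonferroni thresholds reproduce the published arithmetic", {
  expect_equal(signif(bonferroni_threshold(1815), 3), 2.75e-5)
  expect_equal(signif(bonferroni_threshold(1171), 3), 4.27e-5)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 2.5e-3)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("summaries recompute percentages from counts and correlate populations", {
  expect_equal(percent_significant(732, 1815), 40.3)
  expect_error(percent_significant(5, 0), "n_tested")
  expect_error(percent_significant(10, 5), "n_significant")

  set.seed(117)
  res <- do.call(rbind, lapply(1:50, function(i) {
    e <- effect_estimate(paste0("P", i), rnorm(1), runif(1, 0.05, 0.2),
                         n_cases = 50, n_controls = 200)
    e$phecode <- paste0("P", i)
    e$category <- sample(c("catA", "catB"), 1)
    e
  }))
  out <- summarize_phewas(list(EUR = res, AFR = res))
  expect_equal(out$correlations$r, 1.0)
  pp <- out$per_population
  expect_equal(pp$percent_significant,
               percent_significant(pp$n_significant, pp$n_tested))
  expect_equal(out$overlap$n_sig_both, pp$n_significant[1])
  expect_error(summarize_phewas(list()), "empty")
})
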