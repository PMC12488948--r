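test_that("AUC equals the exhaustive pair-ranking probability", {
  # cases {3, 2}, controls {1, 2}: (1 + 1 + 1 + 0.5) / 4
  got <- compute_auc(c(1, 1, 0, 0), c(3, 2, 1, 2))
  expect_equal(got$auc, 0.875)
  # perfect separation and constant score
  expect_equal(compute_auc(c(1, 1, 0), c(5, 4, 1))$auc, 1.0)
  expect_equal(compute_auc(c(1, 0, 1, 0), rep(2, 4))$auc, 0.5)
  expect_error(compute_auc(c(1, 1), c(1, 2)), "both classes")

  set.seed(51)
  for (r in 1:10) {
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, 0.4)
    if (all(y == 1) || all(y == 0)) next
    s <- sample(1:5, n, replace = TRUE)  # ties likely
    pairs <- expand.grid(ca = which(y == 1), co = which(y == 0))
    oracle <- mean(ifelse(s[pairs$ca] > s[pairs$co], 1,
                          ifelse(s[pairs$ca] == s[pairs$co], 0.5, 0)))
    expect_equal(compute_auc(y, s)$auc, oracle)
  }
})

test_that("DeLong interval contains the AUC point estimate", {
  set.seed(52)
  y <- rbinom(300, 1, 0.3)
  s <- rnorm(300) + y
  got <- compute_auc(y, s)
  expect_true(got$ci_low <= got$auc && got$auc <= got$ci_high)
})

test_that("covariate-free category ORs equal the 2x2 cross-product ratios", {
  # top decile 30 cases / 70 controls vs reference 10 cases / 90 controls
  status <- c(rep("case", 30), rep("control", 70),
              rep("case", 10), rep("control", 90))
  z <- c(rnorm(100, 10), rnorm(100, 0))  # separates the two categories
  ss <- make_score_set(z, status)
  ss$percentile_category <- factor(rep(c("90-100", "40-60"), each = 100),
                                   levels = t2dprs:::PERCENTILE_LABELS)
  cohort <- data.frame(id = ss$id, population = "EUR", study = "S1",
                       status = status)
  res <- category_or(ss, cohort, covariates = character(0))
  top <- res[res$label == "90-100", ]
  expect_equal(top$or, (30 * 90) / (70 * 10), tolerance = 1e-6)
  # a category with the same case proportion as the reference: OR ~ 1
  status2 <- rep(c("case", "control"), times = c(20, 80))
  ss2 <- make_score_set(c(z, rnorm(100, 20)), c(status, status2))
  ss2$percentile_category <- factor(rep(c("90-100", "40-60", "0-10"),
                                        each = 100),
                                    levels = t2dprs:::PERCENTILE_LABELS)
  cohort2 <- data.frame(id = ss2$id, population = "EUR", study = "S1",
                        status = c(status, status2))
  res2 <- category_or(ss2, cohort2, covariates = character(0))
  expect_equal(res2$or[res2$label == "0-10"], (20 * 90) / (80 * 10),
               tolerance = 1e-6)

  # zero cell: flagged, others still returned
  status3 <- c(status, rep("control", 50))
  ss3 <- make_score_set(c(z, rnorm(50, -20)), status3)
  ss3$percentile_category <- factor(c(rep(c("90-100", "40-60"), each = 100),
                                      rep("0-10", 50)),
                                    levels = t2dprs:::PERCENTILE_LABELS)
  cohort3 <- data.frame(id = ss3$id, population = "EUR", study = "S1",
                        status = status3)
  res3 <- category_or(ss3, cohort3, covariates = character(0))
  expect_true(res3$flagged[res3$label == "0-10"])
  expect_false(res3$flagged[res3$label == "90-100"])
})

test_that("per-SD OR recovers the simulated effect and excludes prediabetes", {
  sim <- simulate_cohort(quick_config(n = 4000, seed = 61,
                                      context_effects = NULL))
  ss <- prs_pipeline(sim$weight_tables$meta, sim$panel, sim$cohort)
  est <- fit_t2d_model(ss, sim$cohort)
  expect_true(est$ci_low <= 1.78 && 1.78 <= est$ci_high)
  n_pre <- sum(sim$cohort$status == "prediabetes")
  expect_gt(n_pre, 0)
  expect_equal(est$n_cases + est$n_controls, nrow(sim$cohort) - n_pre)
})

test_that("a cohort without controls is rejected", {
  ss <- make_score_set(c(1, 2, 3, 4), c("control", "control", "case", "case"))
  cohort <- data.frame(id = ss$id, population = "EUR", study = "S1",
                       status = c("prediabetes", "prediabetes", "case", "case"),
                       age = 50, sex = 1, bmi = 28)
  ss$status <- cohort$status
  expect_error(fit_t2d_model(ss, cohort, covariates = c("age")),
               "case and one control")
})

test_that("adding the PRS never degrades in-sample AUC beyond tolerance", {
  sim <- simulate_cohort(quick_config(n = 1000, seed = 63))
  ss <- prs_pipeline(sim$weight_tables$meta, sim$panel, sim$cohort)
  a <- auc_improvement(ss, sim$cohort)
  expect_gte(a$delta_auc, -0.005)
  expect_equal(a$auc$model_spec, c("base", "base+PRS", "PRS-alone"))
})

test_that("per-SD OR is invariant to affine rescaling of the raw score", {
  sim <- simulate_cohort(quick_config(n = 800, seed = 67))
  matched <- match_alleles(sim$weight_tables$meta, sim$panel$variants)
  raw <- compute_prs(sim$panel, matched)
  e1 <- fit_t2d_model(standardize_scores(raw, sim$cohort), sim$cohort)
  e2 <- fit_t2d_model(standardize_scores(5 * raw - 2, sim$cohort), sim$cohort)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-8)
})

test_that("age at diagnosis contrasts are mean differences vs the bottom decile", {
  # two categories with means 58 (reference) and 50
  ids <- sprintf("c%03d", 1:40)
  ss <- make_score_set(rnorm(40), rep("control", 40), ids = ids)
  ss$status <- rep("case", 40)
  ss$percentile_category <- factor(rep(c("0-10", "90-100"), each = 20),
                                   levels = t2dprs:::PERCENTILE_LABELS)
  cohort <- data.frame(id = ids, age_at_diagnosis = rep(c(58, 50), each = 20))
  res <- suppressWarnings(age_at_dx_by_category(ss, cohort))
  expect_equal(res$beta[res$label == "90-100"], -8.0, tolerance = 1e-9)

  cohort$age_at_diagnosis <- 55
  res0 <- suppressWarnings(age_at_dx_by_category(ss, cohort))
  expect_equal(res0$beta, 0, tolerance = 1e-9)
})

test_that("category age-at-diagnosis effects match direct group means", {
  sim <- simulate_cohort(quick_config(n = 4000, seed = 71))
  ss <- assign_percentile_categories(
    prs_pipeline(sim$weight_tables$meta, sim$panel, sim$cohort))
  res <- age_at_dx_by_category(ss, sim$cohort)
  cases <- ss$status == "case"
  adx <- sim$cohort$age_at_diagnosis[match(ss$id, sim$cohort$id)]
  means <- tapply(adx[cases], ss$percentile_category[cases], mean)
  oracle <- means - means["0-10"]
  for (lv in res$label) {
    expect_equal(res$beta[res$label == lv], unname(oracle[lv]),
                 tolerance = 1e-9)
  }
})
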