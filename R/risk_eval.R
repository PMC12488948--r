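default_covariates <- function(cohort, covariates) {
  covs <- intersect(covariates, names(cohort))
  missing <- setdiff(covariates, names(cohort))
  if (length(missing)) {
    stop_input("covariate(s) absent from cohort: %s",
               paste(missing, collapse = ", "))
  }
  # a single-study cohort cannot support a study indicator
  if ("study" %in% covs && length(unique(cohort$study)) < 2) {
    covs <- setdiff(covs, "study")
  }
  covs
}

# Assemble the case/control analysis frame: prediabetes excluded.
cc_frame <- function(scores, cohort, covariates) {
  idx <- match(scores$id, cohort$id)
  assert_that(!anyNA(idx), "scores contain ids absent from cohort")
  keep <- scores$status != "prediabetes"
  dat <- data.frame(y = as.integer(scores$status[keep] == "case"),
                    z = scores$z_score[keep],
                    cohort[idx[keep], covariates, drop = FALSE],
                    stringsAsFactors = TRUE)
  if ("study" %in% names(dat)) dat$study <- factor(dat$study)
  if ("population" %in% names(dat)) dat$population <- factor(dat$population)
  assert_that(any(dat$y == 1) && any(dat$y == 0),
              "need at least one case and one control")
  dat
}

#' Per-SD odds ratio of T2D for a standardized PRS
#'
#' Logistic regression of T2D status on the standardized score plus
#' covariates (study entering as categorical indicators). Prediabetes
#' individuals are excluded. The reported effect is the log-OR per control
#' SD of the score with its Wald standard error.
#'
#' @param scores `score_set` from [standardize_scores()].
#' @param cohort cohort `data.frame`.
#' @param covariates covariate columns (default age, sex, BMI, PC1-PC10,
#'   study; the study indicator is dropped automatically when only one
#'   study is present).
#' @param label label for the returned estimate.
#' @return one-row [effect_estimate()] `data.frame`.
#' @export
fit_t2d_model <- function(scores, cohort,
                          covariates = c("age", "sex", "bmi",
                                         sprintf("PC%d", 1:10), "study"),
                          label = "PRS per SD") {
  covs <- default_covariates(cohort, covariates)
  dat <- cc_frame(scores, cohort, covs)
  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                    model = FALSE, y = FALSE)
  coef_estimate(fit, "z", label = label,
                n_cases = sum(dat$y == 1), n_controls = sum(dat$y == 0))
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' The AUC is the probability that a randomly chosen case outranks a
#' randomly chosen control, with ties counting one half; computed via the
#' rank-sum identity. The 95% CI uses the DeLong method.
#'
#' @param status binary (1 = case) or `"case"`/`"control"` vector.
#' @param score risk score or fitted probability, higher = more case-like.
#' @param model_spec free-text model description carried in the result.
#' @return `data.frame` with `auc`, `ci_low`, `ci_high`, `n_cases`,
#'   `n_controls`, `model_spec`.
#' @export
compute_auc <- function(status, score, model_spec = NA_character_) {
  y <- if (is.character(status) || is.factor(status)) {
    as.integer(as.character(status) == "case")
  } else as.integer(status)
  ok <- !is.na(y) & !is.na(score)
  y <- y[ok]; score <- score[ok]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(score)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # pROC warns that a degenerate (AUC = 1) DeLong interval is 1-1; that is
  # the correct degenerate answer, so silence it
  ci <- tryCatch({
    suppressWarnings(suppressMessages(as.numeric(pROC::ci.auc(
      pROC::roc(y, score, quiet = TRUE, direction = "<"),
      method = "delong"
    ))))
  }, error = function(e) c(NA_real_, auc, NA_real_))
  data.frame(auc = auc, ci_low = ci[1], ci_high = ci[3],
             n_cases = n1, n_controls = n0, model_spec = model_spec,
             stringsAsFactors = FALSE)
}

#' AUC of base, base + PRS and PRS-alone risk models
#'
#' Fits logistic models of T2D status on the covariates alone, covariates
#' plus the standardized PRS, and the PRS alone, and returns the in-sample
#' AUC of each with the increment from adding the PRS.
#'
#' @inheritParams fit_t2d_model
#' @return list with `auc` (3-row `data.frame`) and `delta_auc`
#'   (`AUC(base + PRS) - AUC(base)`).
#' @export
auc_improvement <- function(scores, cohort,
                            covariates = c("age", "sex", "bmi",
                                           sprintf("PC%d", 1:10), "study")) {
  covs <- default_covariates(cohort, covariates)
  dat <- cc_frame(scores, cohort, covs)
  base <- stats::glm(y ~ . - z, data = dat, family = stats::binomial())
  full <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  res <- rbind(
    compute_auc(dat$y, stats::fitted(base), "base"),
    compute_auc(dat$y, stats::fitted(full), "base+PRS"),
    compute_auc(dat$y, dat$z, "PRS-alone")
  )
  list(auc = res, delta_auc = res$auc[2] - res$auc[1])
}

#' Odds ratios by PRS percentile category
#'
#' One logistic model with percentile-category indicators (reference
#' category releveled as requested) plus covariates; returns one estimate
#' per non-reference category. Categories empty in either class are
#' flagged, the others still returned.
#'
#' @param scores `score_set` with `percentile_category` (see
#'   [assign_percentile_categories()]).
#' @param cohort cohort `data.frame`.
#' @param reference reference category (default `"40-60"`).
#' @param covariates covariate columns; use `character(0)` for the
#'   covariate-free model (whose estimates equal the 2x2 cross-product
#'   odds ratios exactly).
#' @return [effect_estimate()] rows, one per non-reference category.
#' @export
category_or <- function(scores, cohort, reference = "40-60",
                        covariates = c("age", "sex", "bmi",
                                       sprintf("PC%d", 1:10), "study")) {
  assert_that("percentile_category" %in% names(scores),
              "scores lack percentile_category; run assign_percentile_categories()")
  covs <- if (length(covariates)) default_covariates(cohort, covariates)
          else character(0)
  dat <- cc_frame(scores, cohort, covs)
  dat$cat <- factor(as.character(scores$percentile_category[
    scores$status != "prediabetes"]), levels = PERCENTILE_LABELS)
  assert_that(reference %in% levels(dat$cat), "unknown reference category")
  ref_cases <- sum(dat$y == 1 & dat$cat == reference)
  ref_ctrls <- sum(dat$y == 0 & dat$cat == reference)
  assert_that(ref_cases > 0 && ref_ctrls > 0,
              "reference category must contain cases and controls")
  dat$cat <- stats::relevel(dat$cat, ref = reference)
  dat$z <- NULL
  present <- levels(droplevels(dat$cat))
  fit <- stats::glm(y ~ ., data = droplevels(dat),
                    family = stats::binomial(), model = FALSE, y = FALSE)
  out <- list()
  for (lv in setdiff(PERCENTILE_LABELS, reference)) {
    n_ca <- sum(dat$y == 1 & dat$cat == lv)
    n_co <- sum(dat$y == 0 & dat$cat == lv)
    if (!lv %in% present || n_ca == 0 || n_co == 0) {
      out[[lv]] <- effect_estimate(lv, NA_real_, NA_real_, n_ca, n_co,
                                   flagged = TRUE,
                                   note = "empty or single-class category")
      next
    }
    out[[lv]] <- coef_estimate(fit, paste0("cat", lv), label = lv,
                               n_cases = n_ca, n_controls = n_co)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Age at diagnosis by PRS percentile category (cases only)
#'
#' Linear regression of age at T2D diagnosis on percentile-category
#' indicators among cases; each coefficient is the mean difference in years
#' versus the reference category (default the bottom 0-10% decile).
#'
#' @param scores `score_set` with `percentile_category`.
#' @param cohort cohort with `age_at_diagnosis` (years, cases only).
#' @param reference reference category (default `"0-10"`).
#' @return [effect_estimate()] rows (linear scale), one per non-reference
#'   category with cases; `n_cases` is the category's case count.
#' @export
age_at_dx_by_category <- function(scores, cohort, reference = "0-10") {
  assert_that("percentile_category" %in% names(scores),
              "scores lack percentile_category")
  idx <- match(scores$id, cohort$id)
  keep <- scores$status == "case" & !is.na(cohort$age_at_diagnosis[idx])
  dat <- data.frame(
    age_dx = cohort$age_at_diagnosis[idx[keep]],
    cat = factor(as.character(scores$percentile_category[keep]),
                 levels = PERCENTILE_LABELS)
  )
  assert_that(sum(dat$cat == reference) > 0, "reference category is empty")
  assert_that(length(unique(dat$cat)) >= 2,
              "need cases in at least 2 categories")
  dat$cat <- stats::relevel(droplevels(dat$cat), ref = reference)
  fit <- stats::lm(age_dx ~ cat, data = dat)
  out <- list()
  for (lv in setdiff(levels(dat$cat), reference)) {
    out[[lv]] <- coef_estimate(fit, paste0("cat", lv), label = lv,
                               n_cases = sum(dat$cat == lv),
                               n_controls = 0L, exponentiate = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
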