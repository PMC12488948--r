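#' Define a context variable for stratified analyses
#'
#' @param variable cohort column name.
#' @param breaks optional numeric cut-points for a continuous context
#'   (strata are `cut(..., right = FALSE)` intervals); `NULL` treats the
#'   column's distinct values as categorical strata.
#' @param labels optional stratum labels matching `breaks`.
#' @param drop_covariates covariates to omit within strata (e.g., `"sex"`
#'   in sex-stratified analyses).
#' @param min_cases,min_controls per-stratum counts below which the
#'   stratum's estimate is flagged (default 100/100, mirroring the
#'   meta-analysis eligibility rule).
#' @return a `context_spec` list.
#' @export
context_spec <- function(variable, breaks = NULL, labels = NULL,
                         drop_covariates = character(0),
                         min_cases = 100, min_controls = 100) {
  structure(list(variable = variable, breaks = breaks, labels = labels,
                 drop_covariates = drop_covariates,
                 min_cases = min_cases, min_controls = min_controls),
            class = "context_spec")
}

context_strata <- function(cohort, spec) {
  x <- cohort[[spec$variable]]
  assert_that(!is.null(x), "context variable '%s' absent from cohort",
              spec$variable)
  if (is.null(spec$breaks)) {
    factor(x)
  } else {
    cut(x, breaks = c(-Inf, spec$breaks, Inf), right = FALSE,
        labels = spec$labels)
  }
}

#' Per-SD PRS effect within context strata
#'
#' One logistic per-SD estimate per stratum of the context variable,
#' adjusted for the covariates minus any listed in the spec's
#' `drop_covariates` (sex is never a covariate inside sex strata). Strata
#' below the spec's minimum case/control counts are flagged; strata with a
#' single outcome class are flagged and skipped.
#'
#' @param scores `score_set`.
#' @param cohort cohort `data.frame`.
#' @param spec a [context_spec()].
#' @param covariates base covariate set.
#' @return [effect_estimate()] rows, one per stratum.
#' @export
stratified_estimates <- function(scores, cohort, spec,
                                 covariates = c("age", "sex", "bmi",
                                                sprintf("PC%d", 1:10),
                                                "study")) {
  strata <- context_strata(cohort, spec)
  levs <- levels(strata)
  assert_that(length(levs) >= 2, "need >= 2 strata")
  covs <- setdiff(covariates, c(spec$drop_covariates, spec$variable))
  out <- list()
  for (lv in levs) {
    in_s <- !is.na(strata) & strata == lv
    sub_cohort <- cohort[in_s, , drop = FALSE]
    sub_scores <- scores[scores$id %in% sub_cohort$id, , drop = FALSE]
    n_ca <- sum(sub_scores$status == "case")
    n_co <- sum(sub_scores$status == "control")
    if (n_ca == 0 || n_co == 0) {
      out[[lv]] <- effect_estimate(lv, NA_real_, NA_real_, n_ca, n_co,
                                   flagged = TRUE, note = "single-class stratum")
      next
    }
    est <- fit_t2d_model(sub_scores, sub_cohort,
                         covariates = default_covariates(sub_cohort, covs),
                         label = lv)
    if (n_ca < spec$min_cases || n_co < spec$min_controls) {
      est$flagged <- TRUE
      est$note <- sprintf("below %d cases / %d controls",
                          spec$min_cases, spec$min_controls)
    }
    out[[lv]] <- est
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cochran's Q heterogeneity test
#'
#' Inverse-variance-weighted heterogeneity of k estimates: with weights
#' `w_i = 1/se_i^2` and pooled mean `b = sum(w*beta)/sum(w)`,
#' `Q = sum(w * (beta - b)^2)` is chi-square with k - 1 df under
#' homogeneity. The between-stratum variance tau^2 uses the
#' DerSimonian-Laird moment estimator
#' `max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`, and
#' `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param estimates `data.frame` with columns `beta` and `se` (rows with
#'   missing or non-finite values are dropped), or a numeric vector of
#'   betas with `se` supplied separately.
#' @param se standard errors when `estimates` is a bare numeric vector.
#' @return `data.frame` with `Q`, `df`, `p_het`, `tau2`, `i2`, `k`,
#'   `pooled_beta`.
#' @export
cochran_q <- function(estimates, se = NULL) {
  if (is.numeric(estimates) && !is.null(se)) {
    beta <- estimates
  } else {
    beta <- estimates$beta
    se <- estimates$se
  }
  ok <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[ok]; se <- se[ok]
  k <- length(beta)
  assert_that(k >= 2, "need >= 2 estimates with finite SEs")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - pooled)^2)
  df <- k - 1
  p <- stats::pchisq(Q, df, lower.tail = FALSE)
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  data.frame(Q = Q, df = df, p_het = p, tau2 = tau2, i2 = i2, k = k,
             pooled_beta = pooled)
}

#' PRS-by-context interaction likelihood ratio test
#'
#' Compares the covariate-adjusted logistic model with and without
#' PRS x context interaction term(s), both including the main effects of
#' the score and the context. The statistic is `2 * (ll_full - ll_reduced)`
#' on as many df as interaction terms.
#'
#' @param scores `score_set`.
#' @param cohort cohort `data.frame`.
#' @param spec a [context_spec()].
#' @param covariates base covariates (the context variable and its
#'   `drop_covariates` are removed from the adjustment set).
#' @return `data.frame` with one row per interaction term (`gamma`, `se`)
#'   plus `lrt`, `df`, `p` (identical across rows of one test).
#' @export
interaction_lrt <- function(scores, cohort, spec,
                            covariates = c("age", "sex", "bmi",
                                           sprintf("PC%d", 1:10), "study")) {
  strata <- context_strata(cohort, spec)
  assert_that(length(unique(stats::na.omit(strata))) >= 2,
              "context variable is constant")
  covs <- setdiff(covariates, c(spec$drop_covariates, spec$variable))
  covs <- default_covariates(cohort, covs)
  idx <- match(scores$id, cohort$id)
  keep <- scores$status != "prediabetes" & !is.na(strata[idx])
  dat <- data.frame(y = as.integer(scores$status[keep] == "case"),
                    z = scores$z_score[keep],
                    ctx = droplevels(strata[idx[keep]]),
                    cohort[idx[keep], covs, drop = FALSE])
  if ("study" %in% names(dat)) dat$study <- factor(dat$study)
  reduced <- stats::glm(y ~ . , data = dat, family = stats::binomial())
  full <- stats::glm(y ~ . + z:ctx, data = dat, family = stats::binomial())
  df <- length(stats::coef(full)) - length(stats::coef(reduced))
  assert_that(df >= 1, "full and reduced models are identical (0 df)")
  lrt <- as.numeric(2 * (stats::logLik(full) - stats::logLik(reduced)))
  p <- stats::pchisq(lrt, df, lower.tail = FALSE)
  sm <- summary(full)$coefficients
  terms <- grep("^z:ctx", rownames(sm), value = TRUE)
  flagged <- !full$converged || !reduced$converged
  data.frame(term = terms, gamma = sm[terms, 1], se = sm[terms, 2],
             lrt = lrt, df = df, p = p, flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PRS associations with diabetes-related traits
#'
#' Per-SD effect of the standardized score on each trait within a T2D
#' status subgroup: linear regression (beta, with the R-squared increment
#' over the covariate-only model) for continuous traits, logistic (OR,
#' with AUC) for binary traits. Significance is Bonferroni-corrected for
#' the number of traits in the family.
#'
#' @param scores `score_set`.
#' @param cohort cohort `data.frame` containing the trait columns.
#' @param traits character vector of trait column names.
#' @param subgroup `"controls"` (default), `"cases"`, or `"prediabetes"`.
#' @param n_traits_for_bonferroni divisor for the significance threshold
#'   (default 20).
#' @param log_transform traits to log-transform before fitting.
#' @param covariates adjustment set.
#' @return [effect_estimate()] rows with added `r2_increment` (continuous),
#'   `auc` (binary), `threshold` and `significant` columns; all-missing
#'   traits are skipped with a warning.
#' @export
associate_traits <- function(scores, cohort, traits,
                             subgroup = c("controls", "cases", "prediabetes"),
                             n_traits_for_bonferroni = 20,
                             log_transform = character(0),
                             covariates = c("age", "sex", "bmi",
                                            sprintf("PC%d", 1:10), "study")) {
  subgroup <- match.arg(subgroup)
  status_want <- c(controls = "control", cases = "case",
                   prediabetes = "prediabetes")[subgroup]
  thr <- bonferroni_threshold(n_traits_for_bonferroni)
  idx <- match(scores$id, cohort$id)
  keep <- scores$status == status_want
  covs <- default_covariates(cohort[idx[keep], , drop = FALSE], covariates)
  out <- list()
  for (tr in traits) {
    y <- cohort[[tr]][idx[keep]]
    if (is.null(y) || all(is.na(y))) {
      warning(sprintf("trait '%s' all-missing; skipped", tr), call. = FALSE)
      next
    }
    if (tr %in% log_transform) y <- log(y)
    dat <- data.frame(y = y, z = scores$z_score[keep],
                      cohort[idx[keep], covs, drop = FALSE])
    if ("study" %in% names(dat)) dat$study <- factor(dat$study)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    binary <- length(unique(dat$y)) == 2
    if (binary) {
      dat$y <- as.integer(dat$y == max(dat$y))
      fit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
      est <- coef_estimate(fit, "z", label = tr,
                           n_cases = sum(dat$y), n_controls = sum(1 - dat$y))
      est$auc <- compute_auc(dat$y, stats::fitted(fit))$auc
      est$r2_increment <- NA_real_
    } else {
      fit <- stats::lm(y ~ ., data = dat)
      base <- stats::lm(y ~ . - z, data = dat)
      est <- coef_estimate(fit, "z", label = tr, n_cases = nrow(dat),
                           n_controls = 0L, exponentiate = FALSE)
      est$auc <- NA_real_
      est$r2_increment <- summary(fit)$r.squared - summary(base)$r.squared
    }
    est$threshold <- thr
    est$significant <- !is.na(est$p) & est$p < thr
    out[[tr]] <- est
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
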