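#' Eligibility of an estimate for meta-analysis
#'
#' An input estimate is eligible iff it carries at least `min_cases` cases
#' and `min_controls` controls; missing counts make it ineligible with the
#' reason recorded.
#'
#' @param estimates [effect_estimate()] rows (needs `n_cases`,
#'   `n_controls`).
#' @param min_cases,min_controls thresholds (default 100 each).
#' @return the input with added `eligible` (logical) and
#'   `ineligible_reason` columns.
#' @export
check_eligibility <- function(estimates, min_cases = 100,
                              min_controls = 100) {
  assert_that(all(c("n_cases", "n_controls") %in% names(estimates)),
              "estimates must carry n_cases and n_controls")
  reason <- rep(NA_character_, nrow(estimates))
  missing <- is.na(estimates$n_cases) | is.na(estimates$n_controls)
  reason[missing] <- "missing counts"
  low <- !missing & (estimates$n_cases < min_cases |
                       estimates$n_controls < min_controls)
  reason[low] <- sprintf("fewer than %d cases or %d controls",
                         min_cases, min_controls)
  estimates$eligible <- is.na(reason)
  estimates$ineligible_reason <- reason
  estimates
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Pools k estimates with weights `1/se^2`; the pooled SE is
#' `1/sqrt(sum(w))` and the two-sided p comes from the normal distribution.
#' Heterogeneity (Q, tau^2, I^2) is computed by [cochran_q()] - the single
#' shared implementation - and reported descriptively alongside the
#' fixed-effect pool. A single input passes through verbatim with the
#' `single_study_passthrough` flag set.
#'
#' @param estimates [effect_estimate()]-style `data.frame` with `beta`,
#'   `se` (and optionally counts); at least one row.
#' @param label label of the pooled estimate.
#' @return one-row `data.frame`: `label`, `beta`, `se`, `z`, `p`, `or`,
#'   `ci_low`, `ci_high`, `k`, `n_cases`, `n_controls`, `Q`, `df_Q`,
#'   `p_het`, `tau2`, `i2`, `single_study_passthrough`.
#' @export
ivw_fixed_effect <- function(estimates, label = "pooled") {
  est <- estimates[is.finite(estimates$beta) & is.finite(estimates$se) &
                     estimates$se > 0, , drop = FALSE]
  k <- nrow(est)
  assert_that(k >= 1, "need >= 1 estimate with finite beta and se")
  sum_counts <- function(x) if (all(is.na(x))) NA_integer_ else
    as.integer(sum(x, na.rm = TRUE))
  n_ca <- sum_counts(est$n_cases %||% NA)
  n_co <- sum_counts(est$n_controls %||% NA)
  if (k == 1) {
    base <- effect_estimate(label, est$beta, est$se, n_ca, n_co)
    het <- data.frame(Q = NA_real_, df_Q = NA_integer_, p_het = NA_real_,
                      tau2 = NA_real_, i2 = NA_real_)
    return(cbind(base[c("label", "beta", "se", "z", "p", "or",
                        "ci_low", "ci_high")],
                 k = 1L, n_cases = n_ca, n_controls = n_co, het,
                 single_study_passthrough = TRUE))
  }
  w <- 1 / est$se^2
  beta <- sum(w * est$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- cochran_q(est)
  base <- effect_estimate(label, beta, se, n_ca, n_co)
  cbind(base[c("label", "beta", "se", "z", "p", "or", "ci_low", "ci_high")],
        k = k, n_cases = n_ca, n_controls = n_co,
        Q = het$Q, df_Q = het$df, p_het = het$p_het, tau2 = het$tau2,
        i2 = het$i2, single_study_passthrough = FALSE)
}

#' Two-stage meta-analysis: within populations, then across
#'
#' Stage 1 pools per-study estimates within each population by
#' [ivw_fixed_effect()] (a single-study population passes through
#' verbatim). Stage 2 pools the stage-1 population estimates into the
#' overall estimate. Ineligible inputs (see [check_eligibility()]) are
#' dropped with their reasons logged, not fatal.
#'
#' @param estimates [effect_estimate()] rows with `population` (and
#'   usually `study`) labels.
#' @param min_cases,min_controls eligibility thresholds applied per input
#'   estimate; set to 0 to disable.
#' @return list with `per_population` (stage-1 pooled rows), `overall`
#'   (stage-2 row), and `dropped` (ineligible inputs with reasons).
#' @export
hierarchical_meta <- function(estimates, min_cases = 100,
                              min_controls = 100) {
  assert_that("population" %in% names(estimates),
              "estimates must carry a population label")
  checked <- check_eligibility(estimates, min_cases, min_controls)
  dropped <- checked[!checked$eligible, , drop = FALSE]
  ok <- checked[checked$eligible, , drop = FALSE]
  assert_that(nrow(ok) >= 1, "no eligible estimates")
  pops <- unique(ok$population)
  per_pop <- do.call(rbind, lapply(pops, function(p) {
    r <- ivw_fixed_effect(ok[ok$population == p, , drop = FALSE], label = p)
    r$population <- p
    r
  }))
  overall <- ivw_fixed_effect(per_pop, label = "all populations")
  list(per_population = per_pop, overall = overall, dropped = dropped)
}
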