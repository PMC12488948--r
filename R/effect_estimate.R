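#' Construct an effect-estimate record
#'
#' Uniform container for stratum-, category-, trait- or study-level effects:
#' a log odds ratio (or linear beta), its Wald standard error, the two-sided
#' normal p-value, the exponentiated effect with a 95% confidence interval,
#' and case/control counts. All downstream heterogeneity and meta-analysis
#' routines consume rows of this shape.
#'
#' @param label character label for the stratum/trait/category.
#' @param beta point estimate (log-OR for logistic fits, raw units for
#'   linear fits).
#' @param se Wald standard error of `beta`.
#' @param n_cases,n_controls non-negative counts behind the estimate (for a
#'   linear model, `n_controls` may be 0 and `n_cases` the sample size).
#' @param population,study optional grouping labels.
#' @param flagged logical; `TRUE` marks estimates from degenerate or
#'   non-converged fits, which are reported but never silently used.
#' @param note free-text reason accompanying a flag.
#' @param exponentiate if `FALSE` the `or`/`ci` columns are returned on the
#'   linear scale (for continuous outcomes).
#' @return one-row `data.frame` with columns `label`, `beta`, `se`, `z`,
#'   `p`, `or`, `ci_low`, `ci_high`, `n_cases`, `n_controls`, `population`,
#'   `study`, `flagged`, `note`.
#' @export
effect_estimate <- function(label, beta, se, n_cases = NA_integer_,
                            n_controls = NA_integer_,
                            population = NA_character_, study = NA_character_,
                            flagged = FALSE, note = NA_character_,
                            exponentiate = TRUE) {
  assert_that(length(beta) == 1L && length(se) == 1L,
              "effect_estimate() expects scalar beta/se")
  if (!is.na(n_cases)) assert_that(n_cases >= 0, "n_cases must be >= 0")
  if (!is.na(n_controls)) assert_that(n_controls >= 0, "n_controls must be >= 0")
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  lo <- beta - 1.96 * se
  hi <- beta + 1.96 * se
  if (exponentiate) {
    est <- exp(beta); lo <- exp(lo); hi <- exp(hi)
  } else {
    est <- beta
  }
  data.frame(
    label = as.character(label), beta = beta, se = se, z = z, p = p,
    or = est, ci_low = lo, ci_high = hi,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    population = population, study = study,
    flagged = flagged, note = note,
    stringsAsFactors = FALSE
  )
}

# Extract (beta, se) from a fitted glm/lm for a named coefficient, with
# separation / non-convergence detection for logistic fits.
coef_estimate <- function(fit, term, label, n_cases = NA, n_controls = NA,
                          population = NA_character_, study = NA_character_,
                          exponentiate = TRUE, beta_limit = 15) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    return(effect_estimate(label, NA_real_, NA_real_, n_cases, n_controls,
                           population, study, flagged = TRUE,
                           note = sprintf("term '%s' not estimable", term),
                           exponentiate = exponentiate))
  }
  beta <- sm[term, 1]; se <- sm[term, 2]
  flagged <- FALSE; note <- NA_character_
  if (inherits(fit, "glm")) {
    if (!fit$converged) { flagged <- TRUE; note <- "non-convergence" }
    if (abs(beta) > beta_limit) { flagged <- TRUE; note <- "possible separation" }
  }
  effect_estimate(label, beta, se, n_cases, n_controls, population, study,
                  flagged = flagged, note = note, exponentiate = exponentiate)
}
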