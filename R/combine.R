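#' Assign cross-validation folds within population-by-study cells
#'
#' Folds are balanced (sizes differ by at most 1) within every population x
#' study cell and the assignment is keyed by a stable hash of the
#' individual id plus the seed, so the result is independent of row order.
#'
#' @param cohort cohort `data.frame` with `id`, `population`, `study`.
#' @param k number of folds (default 3).
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..k`, named by individual id.
#' @export
make_cv_folds <- function(cohort, k = 3, seed = 1L) {
  assert_that(k >= 2, "k must be >= 2")
  cell <- paste(cohort$population, cohort$study, sep = ":")
  fold <- stats::setNames(integer(nrow(cohort)), cohort$id)
  for (cl in sort(unique(cell))) {
    in_cl <- cell == cl
    n <- sum(in_cl)
    if (n < k) stop_input("cell '%s' has %d individual(s); k = %d", cl, n, k)
    ids <- sort(cohort$id[in_cl])
    rng <- derive_seed(seed, cl)
    perm <- withr_seed_sample(rng, length(ids))
    labels <- rep(seq_len(k), length.out = n)
    fold[ids[perm]] <- labels
  }
  fold[cohort$id]
}

# sample a permutation under a local, restored RNG state
withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' Fit non-negative combination weights by iterative elimination
#'
#' Fits a logistic regression of T2D status on all population-specific
#' standardized scores (plus intercept). All predictors whose fitted
#' coefficient is not strictly positive are removed and the model refitted,
#' until every remaining slope coefficient is > 0 or no predictors remain.
#' The retained coefficients are the combination weights.
#'
#' @param validation_scores numeric matrix (individuals x source
#'   populations) of standardized population-specific scores.
#' @param status binary vector (1 = case) or character
#'   (`"case"`/`"control"`) aligned with the rows.
#' @param one_at_a_time if `TRUE`, remove only the most negative
#'   coefficient per iteration instead of all negative ones.
#' @param beta_limit absolute coefficient above which separation is
#'   suspected and the fit flagged.
#' @return a `prs_combination` list: `weights` (named, all > 0), `dropped`
#'   (`data.frame` of removed predictors with the iteration and coefficient),
#'   `intercept`, `iterations`, `converged`, `flagged`, `note`.
#' @export
fit_nonneg_weights <- function(validation_scores, status,
                               one_at_a_time = FALSE, beta_limit = 15) {
  X <- as.matrix(validation_scores)
  assert_that(!is.null(colnames(X)), "validation_scores needs column names")
  y <- if (is.character(status) || is.factor(status)) {
    as.integer(as.character(status) == "case")
  } else as.integer(status)
  assert_that(length(y) == nrow(X), "status length must match score rows")
  assert_that(any(y == 1) && any(y == 0),
              "need at least one case and one control")

  active <- colnames(X)
  dropped <- data.frame(population = character(0), coefficient = numeric(0),
                        iteration = integer(0), stringsAsFactors = FALSE)
  iter <- 0L; flagged <- FALSE; note <- NA_character_
  intercept <- NA_real_; converged <- TRUE
  while (length(active) > 0) {
    iter <- iter + 1L
    dat <- data.frame(y = y, X[, active, drop = FALSE], check.names = FALSE)
    fit <- stats::glm(y ~ ., data = dat, family = stats::binomial(),
                      model = FALSE, y = FALSE)
    converged <- fit$converged
    cf <- stats::coef(fit)
    intercept <- cf[["(Intercept)"]]
    slopes <- cf[setdiff(names(cf), "(Intercept)")]
    names(slopes) <- active
    if (!converged || any(abs(slopes) > beta_limit)) {
      flagged <- TRUE
      note <- if (!converged) "non-convergence" else "possible separation"
    }
    neg <- slopes[!(slopes > 0)]   # coefficient exactly 0 is removed too
    if (length(neg) == 0) {
      return(structure(list(weights = slopes, dropped = dropped,
                            intercept = intercept, iterations = iter,
                            converged = converged, flagged = flagged,
                            note = note),
                       class = "prs_combination"))
    }
    if (one_at_a_time) neg <- neg[which.min(neg)]
    dropped <- rbind(dropped,
                     data.frame(population = names(neg),
                                coefficient = unname(neg),
                                iteration = iter, stringsAsFactors = FALSE))
    active <- setdiff(active, names(neg))
  }
  structure(list(weights = stats::setNames(numeric(0), character(0)),
                 dropped = dropped, intercept = intercept,
                 iterations = iter, converged = converged,
                 flagged = TRUE,
                 note = "all predictors eliminated"),
            class = "prs_combination")
}

#' @export
print.prs_combination <- function(x, ...) {
  cat("<prs_combination>\n")
  if (length(x$weights)) {
    cat("  weights:\n")
    for (p in names(x$weights)) cat(sprintf("    %s: %.4f\n", p, x$weights[p]))
  } else cat("  no retained predictors\n")
  if (nrow(x$dropped)) {
    cat(sprintf("  dropped: %s\n", paste(x$dropped$population, collapse = ", ")))
  }
  cat(sprintf("  iterations: %d, converged: %s%s\n", x$iterations,
              x$converged, if (isTRUE(x$flagged)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Apply combination weights to population-specific scores
#'
#' The combined PRS is the weighted sum over retained source populations;
#' populations dropped during fitting contribute 0. The intercept is not
#' used.
#'
#' @param test_scores numeric matrix (individuals x source populations).
#' @param weights a `prs_combination` (or bare named numeric vector).
#' @return numeric vector of combined scores, named by row names.
#' @export
linear_combination_score <- function(test_scores, weights) {
  w <- if (inherits(weights, "prs_combination")) weights$weights else weights
  X <- as.matrix(test_scores)
  if (length(w) == 0) return(stats::setNames(rep(0, nrow(X)), rownames(X)))
  missing <- setdiff(names(w), colnames(X))
  if (length(missing)) {
    stop_input("weight for population(s) absent from test scores: %s",
               paste(missing, collapse = ", "))
  }
  stats::setNames(as.numeric(X[, names(w), drop = FALSE] %*% w), rownames(X))
}

#' Cross-validated non-negative linear combination of PRS
#'
#' Three-fold (by default) cross-validation within population x study
#' cells: for each fold, combination weights are learned on the other
#' folds (the validation set) with [fit_nonneg_weights()] and applied to
#' the held-out fold, so every individual receives exactly one combined
#' score from a model not fit on them. Combined scores are then
#' control-standardized.
#'
#' @param cohort cohort `data.frame` (`id`, `population`, `study`,
#'   `status`).
#' @param score_matrix numeric matrix (individuals x source populations) of
#'   standardized population-specific scores, rownames = ids.
#' @param k folds (default 3).
#' @param seed seed for fold assignment.
#' @param group_by standardization grouping for the final combined score
#'   (default `"population"`).
#' @return list with `scores` (a `score_set` of the combined PRS), `fits`
#'   (per-fold `prs_combination`s) and `folds`.
#' @export
cross_validated_combination <- function(cohort, score_matrix, k = 3,
                                        seed = 1L, group_by = "population") {
  X <- as.matrix(score_matrix)
  assert_that(all(cohort$id %in% rownames(X)),
              "score_matrix must cover every cohort individual")
  X <- X[cohort$id, , drop = FALSE]
  folds <- make_cv_folds(cohort, k = k, seed = seed)
  cc <- cohort$status != "prediabetes"
  combined <- stats::setNames(rep(NA_real_, nrow(cohort)), cohort$id)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    val <- folds != f & cc   # fit on the other folds, cases/controls only
    fit <- fit_nonneg_weights(X[val, , drop = FALSE], cohort$status[val])
    if (isTRUE(fit$flagged) && length(fit$weights) == 0 &&
        identical(fit$note, "all predictors eliminated")) {
      # legitimate degenerate outcome: combined score 0 for this fold
      warning(sprintf("fold %d: all predictors eliminated", f), call. = FALSE)
    } else if (isTRUE(fit$flagged)) {
      stop_input("fold %d fit failed: %s", f, fit$note)
    }
    fits[[f]] <- fit
    test <- folds == f
    combined[test] <- linear_combination_score(X[test, , drop = FALSE], fit)
  }
  scores <- standardize_scores(combined, cohort, group_by = group_by)
  list(scores = scores, fits = fits, folds = folds)
}

#' Write per-fold combination weights to JSON
#'
#' @param fits list of `prs_combination` objects (one per fold).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_combination_json <- function(fits, path) {
  payload <- lapply(seq_along(fits), function(f) {
    x <- fits[[f]]
    list(fold = f, weights = as.list(x$weights),
         dropped = x$dropped$population, intercept = x$intercept,
         iterations = x$iterations, converged = x$converged,
         flagged = isTRUE(x$flagged))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
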