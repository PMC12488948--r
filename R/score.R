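PERCENTILE_LABELS <- c("0-10", "10-20", "20-40", "40-60", "60-80",
                       "80-90", "90-100")
PERCENTILE_PROBS <- c(0.10, 0.20, 0.40, 0.60, 0.80, 0.90)

#' Compute raw polygenic risk scores
#'
#' The PRS for each individual is the weighted sum over matched variants of
#' the effect-allele dosage: the alt-allele dosage for `direct`/`flip`
#' orientations, `2 - alt dosage` for `swap`/`swap_flip`. Missing dosages
#' are mean-imputed from the panel's per-variant dosage mean (the behaviour
#' of standard scoring tools).
#'
#' @param panel a [dosage_panel()] (or any list with a samples x variants
#'   `dosages` matrix and a `variants` data.frame).
#' @param matched output of [match_alleles()]; only rows with
#'   `exclude_reason == "none"` are used, and at least one is required.
#' @return named numeric vector of raw scores, one per sample.
#' @export
compute_prs <- function(panel, matched) {
  use <- matched[matched$exclude_reason == "none", , drop = FALSE]
  assert_that(nrow(use) > 0,
              "no usable matched variants: raw PRS is undefined")
  dos <- panel$dosages[, use$panel_index, drop = FALSE]
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    for (j in seq_len(ncol(dos))) {
      miss <- is.na(dos[, j])
      if (any(miss)) dos[miss, j] <- mu[j]
    }
  }
  swap <- use$orientation %in% c("swap", "swap_flip")
  if (any(swap)) dos[, swap] <- 2 - dos[, swap, drop = FALSE]
  scores <- as.numeric(dos %*% use$effect_weight)
  names(scores) <- rownames(panel$dosages)
  scores
}

#' Standardize raw scores against the control distribution
#'
#' Within each standardization group (by default the population label) the
#' control mean and sample standard deviation (n - 1 denominator) of the
#' raw score are computed, and every individual in the group - cases,
#' controls and prediabetes alike - is standardized with those control
#' parameters. One z-unit therefore corresponds to one control standard
#' deviation within the group.
#'
#' @param raw named numeric vector of raw scores (names = individual ids).
#' @param cohort cohort `data.frame` with columns `id`, `status`
#'   (`case`/`control`/`prediabetes`), `population`, `study`.
#' @param group_by character vector of cohort columns defining the
#'   standardization groups (default `"population"`; use
#'   `c("population", "study")` for per-study anchoring).
#' @return a `score_set`: `data.frame` with `id`, `population`, `study`,
#'   `status`, `raw_score`, `z_score`, plus a `"standardization"` attribute
#'   holding per-group control means/SDs.
#' @export
standardize_scores <- function(raw, cohort, group_by = "population") {
  assert_that(all(c("id", "status") %in% names(cohort)),
              "cohort must have columns id, status")
  assert_that(all(group_by %in% names(cohort)),
              "group_by columns missing from cohort")
  idx <- match(cohort$id, names(raw))
  assert_that(!anyNA(idx), "raw scores missing for some cohort individuals")
  out <- data.frame(id = cohort$id,
                    population = cohort$population %||% NA_character_,
                    study = cohort$study %||% NA_character_,
                    status = cohort$status,
                    raw_score = as.numeric(raw[idx]),
                    stringsAsFactors = FALSE)
  grp <- interaction(cohort[group_by], drop = TRUE, sep = ":")
  params <- data.frame(group = levels(grp), control_mean = NA_real_,
                       control_sd = NA_real_, n_controls = NA_integer_,
                       stringsAsFactors = FALSE)
  out$z_score <- NA_real_
  for (i in seq_along(levels(grp))) {
    g <- levels(grp)[i]
    in_g <- grp == g
    ctrl <- in_g & cohort$status == "control"
    n_ctrl <- sum(ctrl)
    if (n_ctrl < 2) {
      stop_input("group '%s' has %d control(s); >= 2 required", g, n_ctrl)
    }
    m <- mean(out$raw_score[ctrl])
    s <- stats::sd(out$raw_score[ctrl])
    if (!is.finite(s) || s == 0) {
      stop_input("group '%s' has zero control score variance", g)
    }
    out$z_score[in_g] <- (out$raw_score[in_g] - m) / s
    params$control_mean[i] <- m
    params$control_sd[i] <- s
    params$n_controls[i] <- n_ctrl
  }
  out$.group <- as.character(grp)
  attr(out, "standardization") <- params
  attr(out, "group_by") <- group_by
  class(out) <- c("score_set", "data.frame")
  out
}

#' Assign percentile risk categories
#'
#' Cut-points are placed at the 10th, 20th, 40th, 60th, 80th and 90th
#' percentiles of the *control* z-score distribution within each
#' standardization group, yielding the categories 0-10, 10-20, 20-40,
#' 40-60, 60-80, 80-90 and 90-100. Bins are half-open `[low, high)`: a
#' z-score exactly at a cut-point falls in the upper bin.
#'
#' @param scores a `score_set` from [standardize_scores()].
#' @return the `score_set` with an added `percentile_category` factor.
#' @export
assign_percentile_categories <- function(scores) {
  assert_that(inherits(scores, "score_set"),
              "scores must come from standardize_scores()")
  grp <- scores$.group
  cat_out <- rep(NA_character_, nrow(scores))
  for (g in unique(grp)) {
    in_g <- grp == g
    ctrl_z <- scores$z_score[in_g & scores$status == "control"]
    if (length(ctrl_z) < length(PERCENTILE_PROBS) + 1) {
      stop_input("group '%s' has fewer controls than cut-points", g)
    }
    cuts <- stats::quantile(ctrl_z, probs = PERCENTILE_PROBS, names = FALSE)
    bin <- findInterval(scores$z_score[in_g], cuts, left.open = FALSE) + 1L
    cat_out[in_g] <- PERCENTILE_LABELS[bin]
  }
  scores$percentile_category <- factor(cat_out, levels = PERCENTILE_LABELS)
  scores
}

#' Write a score set to TSV
#'
#' @param scores a `score_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  cols <- intersect(c("id", "study", "population", "status", "raw_score",
                      "z_score", "percentile_category"), names(scores))
  utils::write.table(scores[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
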