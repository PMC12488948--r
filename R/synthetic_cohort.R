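# mg/dl per mmol/L of glucose; used for all unit conversion.
MGDL_PER_MMOL <- 18.016

#' Convert glucose between mg/dl and mmol/L
#'
#' Internally all glycemic thresholds are held in mg/dl; these helpers
#' convert measurements supplied or reported in mmol/L (1 mmol/L =
#' 18.016 mg/dl).
#'
#' @param x numeric vector of glucose values.
#' @return converted values.
#' @export
glucose_mmol_to_mgdl <- function(x) x * MGDL_PER_MMOL

#' @rdname glucose_mmol_to_mgdl
#' @export
glucose_mgdl_to_mmol <- function(x) x / MGDL_PER_MMOL

#' Simulation configuration for synthetic multi-population cohorts
#'
#' Bundles and validates all ground-truth parameters of the generator.
#' Defaults emulate the study conditions the package is designed around:
#' four self-identified populations with distinct allele frequencies, a
#' logistic disease model with a per-control-SD PRS log-OR of log(1.78),
#' a modest PRS-by-sex interaction, PRS-correlated HbA1c-like and fasting
#' glucose-like traits, PRS-dependent age at type 2 diabetes diagnosis,
#' and a small phenome mixing PRS-linked and null phecodes across two
#' simulated biobanks.
#'
#' @param populations character vector of population labels.
#' @param n_per_population individuals per population; scalar or named
#'   vector aligned with `populations`.
#' @param n_variants number of biallelic variants.
#' @param maf_range length-2 numeric in (0, 0.5] (or a named list per
#'   population): per-variant MAFs are drawn uniformly in this range,
#'   independently per population, so populations differ in frequency.
#' @param true_beta_prs true log-OR of T2D per *control* standard deviation
#'   of the true score (the scale on which fitted models report effects).
#' @param context_effects named numeric vector of PRS-by-context
#'   interaction log-ORs (gamma); names refer to cohort columns (`sex`) or
#'   create new binary 0/1 context columns.
#' @param trait_effects named numeric vector of per-SD effects (delta) on
#'   quantitative traits; each becomes a `trait_<name>` cohort column.
#' @param trait_noise_sd residual SD of the quantitative traits.
#' @param phenome_spec `data.frame` with columns `phecode`, `log_or`,
#'   `prevalence`: the simulated phenome. Default: a mix of strongly
#'   PRS-linked codes (mirroring diabetes-related phecodes) and null codes
#'   drawn from the bundled synthetic phecode map.
#' @param n_studies number of simulated studies/biobanks.
#' @param age_at_dx_slope change in age at diagnosis (years) per SD of PRS
#'   among cases; negative means earlier diagnosis at higher PRS.
#' @param prediabetes_rate probability a non-case is prediabetic.
#' @param alpha baseline log-odds of T2D at mean covariates (scalar or
#'   named per population).
#' @param covariate_effects list of log-OR effects for `age` (per year,
#'   centered), `sex` (male vs female, centered) and `bmi` (per unit,
#'   centered) in the disease model.
#' @param weight_noise_sd SD of the noise added to the true variant effects
#'   in each population-specific weight table, relative to the SD of the
#'   true effects (the meta table carries the true effects unchanged).
#' @param prop_swap,prop_flip fractions of variants whose emitted weight
#'   table rows are allele-swapped (weight negated) or strand-flipped, to
#'   exercise harmonization.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(populations = c("AFR", "ASN", "EUR", "HIS"),
                       n_per_population = 5000,
                       n_variants = 100,
                       maf_range = c(0.05, 0.5),
                       true_beta_prs = log(1.78),
                       context_effects = c(sex = 0.093),
                       trait_effects = c(hba1c = 0.034,
                                         fasting_glucose = 0.030),
                       trait_noise_sd = 0.5,
                       phenome_spec = NULL,
                       n_studies = 2,
                       age_at_dx_slope = -2.54,
                       prediabetes_rate = 0.04,
                       alpha = -0.94,
                       covariate_effects = list(age = 0.02, sex = 0.25,
                                                bmi = 0.05),
                       weight_noise_sd = 0.5,
                       prop_swap = 0.2, prop_flip = 0.1,
                       seed = 1L) {
  assert_that(length(populations) >= 1, "populations must be non-empty")
  if (length(n_per_population) == 1L) {
    n_per_population <- stats::setNames(rep(n_per_population,
                                            length(populations)), populations)
  }
  assert_that(all(populations %in% names(n_per_population)),
              "n_per_population must name every population")
  assert_that(all(n_per_population >= 1),
              "n_per_population: all counts must be >= 1")
  assert_that(n_variants >= 1, "n_variants must be >= 1")
  if (!is.list(maf_range)) {
    maf_range <- stats::setNames(rep(list(maf_range), length(populations)),
                                 populations)
  }
  for (p in populations) {
    r <- maf_range[[p]]
    assert_that(!is.null(r) && length(r) == 2 && r[1] <= r[2],
                "maf_range for %s must be a (lo, hi) pair", p)
    assert_that(all(r > 0 & r <= 0.5),
                "maf_range for %s must lie in (0, 0.5]", p)
  }
  if (is.null(phenome_spec)) phenome_spec <- default_phenome_spec()
  assert_that(all(c("phecode", "log_or", "prevalence") %in%
                    names(phenome_spec)),
              "phenome_spec needs columns phecode, log_or, prevalence")
  assert_that(all(phenome_spec$prevalence > 0 & phenome_spec$prevalence < 1),
              "phenome_spec: prevalence must be in (0, 1)")
  assert_that(n_studies >= 1, "n_studies must be >= 1")
  assert_that(prediabetes_rate >= 0 && prediabetes_rate < 1,
              "prediabetes_rate must be in [0, 1)")
  if (length(alpha) == 1L) {
    alpha <- stats::setNames(rep(alpha, length(populations)), populations)
  }
  if (is.null(context_effects)) context_effects <- numeric(0)
  if (is.null(trait_effects)) trait_effects <- numeric(0)
  cfg <- list(populations = populations,
              n_per_population = n_per_population,
              n_variants = as.integer(n_variants),
              maf_range = maf_range,
              true_beta_prs = true_beta_prs,
              context_effects = context_effects,
              trait_effects = trait_effects,
              trait_noise_sd = trait_noise_sd,
              phenome_spec = phenome_spec,
              n_studies = as.integer(n_studies),
              age_at_dx_slope = age_at_dx_slope,
              prediabetes_rate = prediabetes_rate,
              alpha = alpha,
              covariate_effects = covariate_effects,
              weight_noise_sd = weight_noise_sd,
              prop_swap = prop_swap, prop_flip = prop_flip,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Default simulated phenome: diabetes-linked codes with effects mirroring
# reported PheWAS magnitudes, plus null codes from other disease categories.
default_phenome_spec <- function() {
  data.frame(
    phecode = c("250.2", "401.1", "272.1", "585.3", "366.2",
                "008", "327.4", "550.2", "703", "939"),
    log_or = c(log(2.38), log(1.34), log(1.27), log(1.34), log(1.27),
               0, 0, 0, 0, 0),
    prevalence = c(0.15, 0.30, 0.20, 0.05, 0.08,
                   0.05, 0.04, 0.03, 0.06, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Dosage panel container
#'
#' @param dosages samples x variants numeric matrix of alt-allele dosages
#'   in \[0, 2\], with sample ids as row names.
#' @param variants `data.frame` with one row per variant: `variant_id`,
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `maf`, `info`, `n`.
#' @return a `dosage_panel` object.
#' @export
dosage_panel <- function(dosages, variants) {
  assert_that(ncol(dosages) == nrow(variants),
              "dosages and variants disagree on variant count")
  assert_that(!is.null(rownames(dosages)), "dosages needs sample id rownames")
  structure(list(dosages = dosages, variants = variants),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("<dosage_panel> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

# Numeric fixed point converting the per-control-SD effect to the
# population-SD scale used inside the generator. The control SD of a
# standardized score is slightly below 1 because high-score individuals
# are preferentially removed as cases; the attenuation is computed by
# integrating the logistic model over the score and the (approximately
# normal) covariate linear predictor.
calibrate_beta <- function(beta_ctrl_sd, alpha, mean_slope_extra = 0,
                           sigma_cov = 0) {
  if (beta_ctrl_sd == 0) return(0)
  z <- seq(-8, 8, length.out = 2001)
  fz <- stats::dnorm(z)
  gh_n <- 15
  cq <- stats::qnorm(seq(0.5 / gh_n, 1 - 0.5 / gh_n, length.out = gh_n))
  control_sd <- function(b) {
    slope <- b + mean_slope_extra
    p_ctrl <- rowMeans(vapply(cq, function(q) {
      1 - stats::plogis(alpha + slope * z + sigma_cov * q)
    }, numeric(length(z))))
    w <- fz * p_ctrl
    w <- w / sum(w)
    m <- sum(w * z)
    sqrt(sum(w * (z - m)^2))
  }
  b <- beta_ctrl_sd
  for (i in 1:8) b <- beta_ctrl_sd / control_sd(b)
  b
}

#' Simulate a multi-population, multi-study cohort with known truth
#'
#' Generates genotype dosages, population-specific and meta variant weight
#' tables, a phenotype/covariate table with ADA-consistent glycemic
#' measurements, and an ICD record stream, all from one seed.
#'
#' Disease status is drawn from a logistic model
#' `logit(p) = alpha_pop + beta * z + sum(gamma_c * z * x_c) + covariates`,
#' where `z` is the true score standardized within population. `beta` is
#' specified per control SD (the reporting scale of all downstream fits)
#' and converted internally to the population-SD scale by a deterministic
#' numeric calibration. Glycemic measurements are generated so that
#' [classify_glycemic_status()] reproduces the drawn status exactly. Among
#' cases, age at diagnosis decreases linearly in the score. Each phenome
#' phecode's ICD codes are emitted with per-person Poisson counts so that
#' count-1 individuals exist, exercising the minimum-count rule.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort` list: `panel` ([dosage_panel()]),
#'   `weight_tables` (one per source population plus `"meta"`), `cohort`
#'   (phenotype/covariate `data.frame`), `icd` (record `data.frame`),
#'   `phecode_map`, and `truth` (all generating parameters).
#' @export
simulate_cohort <- function(config) {
  assert_that(inherits(config, "sim_config"),
              "config must come from sim_config()")
  set.seed(config$seed)
  pops <- config$populations
  n_pop <- config$n_per_population[pops]
  n_total <- sum(n_pop)
  V <- config$n_variants

  ## variants: never palindromic so harmonization is unambiguous by default
  ref <- sample(VALID_ALLELES, V, replace = TRUE)
  alt <- vapply(ref, function(r) {
    sample(setdiff(VALID_ALLELES, c(r, complement_allele(r))), 1)
  }, character(1))
  variants <- data.frame(
    variant_id = sprintf("var%04d", seq_len(V)),
    chrom = rep("1", V), pos = 10000L + 1000L * seq_len(V),
    ref_allele = unname(ref), alt_allele = unname(alt),
    stringsAsFactors = FALSE
  )
  maf <- sapply(pops, function(p) {
    stats::runif(V, config$maf_range[[p]][1], config$maf_range[[p]][2])
  })
  maf <- matrix(maf, nrow = V, dimnames = list(variants$variant_id, pops))

  ## genotypes (alt-allele dosages as allele counts)
  ids <- unlist(lapply(pops, function(p) {
    sprintf("%s_%05d", p, seq_len(n_pop[[p]]))
  }), use.names = FALSE)
  population <- rep(pops, n_pop)
  dos <- matrix(NA_real_, n_total, V,
                dimnames = list(ids, variants$variant_id))
  for (p in pops) {
    rows <- population == p
    dos[rows, ] <- matrix(
      stats::rbinom(sum(rows) * V, 2L, rep(maf[, p], each = sum(rows))),
      ncol = V
    )
  }
  pooled_maf <- colMeans(dos) / 2
  variants$maf <- pmin(pooled_maf, 1 - pooled_maf)
  variants$info <- stats::runif(V, 0.7, 1)
  variants$n <- n_total
  panel <- dosage_panel(dos, variants)

  ## true score, standardized within population
  w_true <- stats::rnorm(V, 0, 0.1)
  raw_true <- as.numeric(dos %*% w_true)
  z <- numeric(n_total)
  for (p in pops) {
    rows <- population == p
    z[rows] <- (raw_true[rows] - mean(raw_true[rows])) / stats::sd(raw_true[rows])
  }

  ## covariates and contexts
  study <- sample(sprintf("S%d", seq_len(config$n_studies)), n_total,
                  replace = TRUE)
  age <- stats::runif(n_total, 40, 85)
  sex <- stats::rbinom(n_total, 1, 0.5)
  bmi <- stats::rnorm(n_total, 28, 5)
  pcs <- matrix(stats::rnorm(n_total * 10), n_total, 10,
                dimnames = list(NULL, sprintf("PC%d", 1:10)))
  pcs[, 1] <- pcs[, 1] + 2 * (match(population, pops) - 1)
  pcs[, 2] <- pcs[, 2] - (match(population, pops) - 1)
  cohort <- data.frame(id = ids, population = population, study = study,
                       age = age, sex = sex, bmi = bmi, pcs,
                       stringsAsFactors = FALSE)
  for (cv in names(config$context_effects)) {
    if (!cv %in% names(cohort)) {
      cohort[[cv]] <- stats::rbinom(n_total, 1, 0.5)
    }
  }

  ## disease model
  ce <- config$covariate_effects
  cov_lp <- ce$age * (age - 62.5) + ce$sex * (sex - 0.5) + ce$bmi * (bmi - 28)
  sigma_cov <- sqrt(ce$age^2 * (85 - 40)^2 / 12 + ce$sex^2 * 0.25 +
                      ce$bmi^2 * 25)
  gam <- config$context_effects
  inter_lp <- numeric(n_total)
  mean_slope_extra <- 0
  for (cv in names(gam)) {
    inter_lp <- inter_lp + gam[[cv]] * z * cohort[[cv]]
    mean_slope_extra <- mean_slope_extra + gam[[cv]] * mean(cohort[[cv]])
  }
  b_pop <- vapply(pops, function(p) {
    calibrate_beta(config$true_beta_prs, config$alpha[[p]],
                   mean_slope_extra, sigma_cov)
  }, numeric(1))
  lp <- config$alpha[population] + b_pop[population] * z + inter_lp + cov_lp
  p_case <- stats::plogis(lp)
  is_case <- stats::rbinom(n_total, 1, p_case) == 1
  is_pre <- !is_case & stats::rbinom(n_total, 1, config$prediabetes_rate) == 1
  status <- ifelse(is_case, "case", ifelse(is_pre, "prediabetes", "control"))

  ## glycemic measurements consistent with the drawn status
  fasting <- stats::runif(n_total, 80, 99)
  random_g <- stats::runif(n_total, 80, 139)
  hba1c <- stats::runif(n_total, 4.8, 5.6)
  ogtt <- rep(NA_real_, n_total)
  diagnosis <- rep(FALSE, n_total)
  fasting[is_case] <- stats::runif(sum(is_case), 126, 180)
  hba1c[is_case] <- stats::runif(sum(is_case), 6.5, 9.5)
  diagnosis[is_case] <- stats::runif(sum(is_case)) < 0.6
  fasting[is_pre] <- stats::runif(sum(is_pre), 100, 125)
  cohort$fasting_glucose <- fasting
  cohort$random_glucose <- random_g
  cohort$hba1c <- hba1c
  cohort$ogtt_2h <- ogtt
  cohort$physician_diagnosis <- diagnosis
  cohort$status <- status

  ## age at diagnosis: linear in the score among cases
  age_dx <- rep(NA_real_, n_total)
  age_dx[is_case] <- pmax(25, 52 + config$age_at_dx_slope * z[is_case] +
                            stats::rnorm(sum(is_case), 0, 4))
  cohort$age_at_diagnosis <- age_dx

  ## quantitative traits
  for (tr in names(config$trait_effects)) {
    cohort[[paste0("trait_", tr)]] <-
      config$trait_effects[[tr]] * z +
      stats::rnorm(n_total, 0, config$trait_noise_sd)
  }

  ## weight tables: noisy population-specific copies plus exact meta table
  sd_w <- stats::sd(w_true)
  orient <- sample(c("direct", "swap", "flip", "swap_flip"), V, replace = TRUE,
                   prob = c((1 - config$prop_swap) * (1 - config$prop_flip),
                            config$prop_swap * (1 - config$prop_flip),
                            (1 - config$prop_swap) * config$prop_flip,
                            config$prop_swap * config$prop_flip))
  make_table <- function(w, source) {
    eff <- variants$alt_allele; oth <- variants$ref_allele
    wt <- w
    swp <- orient %in% c("swap", "swap_flip")
    eff[swp] <- variants$ref_allele[swp]
    oth[swp] <- variants$alt_allele[swp]
    wt[swp] <- -wt[swp]
    flp <- orient %in% c("flip", "swap_flip")
    eff[flp] <- complement_allele(eff[flp])
    oth[flp] <- complement_allele(oth[flp])
    data.frame(variant_id = variants$variant_id, chrom = variants$chrom,
               pos = variants$pos, effect_allele = eff, other_allele = oth,
               effect_weight = wt, source_population = source,
               stringsAsFactors = FALSE)
  }
  weight_tables <- stats::setNames(lapply(pops, function(p) {
    make_table(w_true + stats::rnorm(V, 0, config$weight_noise_sd * sd_w), p)
  }), pops)
  weight_tables$meta <- make_table(w_true, "meta")

  ## ICD records driven by the phenome spec
  pm <- synthetic_phecode_map()
  spec <- config$phenome_spec
  rec_person <- character(0); rec_code <- character(0)
  rec_vocab <- character(0); rec_phe <- character(0)
  for (i in seq_len(nrow(spec))) {
    phe <- spec$phecode[i]
    codes <- pm[pm$phecode == phe, , drop = FALSE]
    if (nrow(codes) == 0) {
      stop_input("phenome_spec phecode %s absent from the synthetic map", phe)
    }
    p_lat <- stats::plogis(stats::qlogis(spec$prevalence[i]) +
                             spec$log_or[i] * z)
    latent <- stats::rbinom(n_total, 1, p_lat) == 1
    counts <- integer(n_total)
    counts[latent] <- stats::rpois(sum(latent), 2.5)
    counts[!latent] <- as.integer(stats::runif(sum(!latent)) < 0.02)
    who <- rep(seq_len(n_total), counts)
    if (length(who)) {
      pick <- 1 + (seq_along(who) %% nrow(codes))
      rec_person <- c(rec_person, ids[who])
      rec_code <- c(rec_code, codes$icd_code[pick])
      rec_vocab <- c(rec_vocab, codes$vocabulary[pick])
      rec_phe <- c(rec_phe, rep(phe, length(who)))
    }
  }
  icd <- data.frame(person_id = rec_person, code = rec_code,
                    vocabulary = rec_vocab,
                    date = "2020-01-01", stringsAsFactors = FALSE)

  structure(list(
    panel = panel,
    weight_tables = weight_tables,
    cohort = cohort,
    icd = icd,
    phecode_map = pm,
    truth = list(w_true = w_true, z = stats::setNames(z, ids),
                 beta_ctrl_sd = config$true_beta_prs, beta_pop_sd = b_pop,
                 gamma = config$context_effects,
                 delta = config$trait_effects,
                 age_at_dx_slope = config$age_at_dx_slope,
                 alpha = config$alpha, maf = maf, orientation = orient,
                 p_case = p_case),
    config = config
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- table(x$cohort$population, x$cohort$status)
  cat(sprintf("<sim_cohort> %d individuals, %d variants, %d studies\n",
              nrow(x$cohort), x$config$n_variants, x$config$n_studies))
  print(tab)
  invisible(x)
}

#' Classify glycemic status from measurements
#'
#' Applies American Diabetes Association-style criteria: a T2D case is an
#' adult (age >= 25) with a physician diagnosis, fasting glucose >= 126
#' mg/dl, random glucose >= 200 mg/dl, or HbA1c >= 6.5%. Prediabetes is a
#' non-case aged >= 18 with fasting glucose 100-125 mg/dl, HbA1c 5.7-6.4%,
#' or a 2-h OGTT of 140-199 mg/dl. Controls are adults >= 40 meeting
#' neither definition; everyone else is unclassified. Missing measurements
#' simply fail their criterion.
#'
#' @param m `data.frame` with columns `age` and any of `fasting_glucose`,
#'   `random_glucose`, `hba1c`, `ogtt_2h` (mg/dl except HbA1c in percent)
#'   and logical `physician_diagnosis`.
#' @return character vector in
#'   `{"case", "prediabetes", "control", "unclassified"}`.
#' @export
classify_glycemic_status <- function(m) {
  assert_that("age" %in% names(m), "age is required")
  assert_that(all(!is.na(m$age)), "age must be present for every individual")
  assert_that(all(m$age >= 0), "age must be >= 0")
  get <- function(col) if (col %in% names(m)) m[[col]] else rep(NA_real_, nrow(m))
  fasting <- get("fasting_glucose"); random_g <- get("random_glucose")
  hba1c <- get("hba1c"); ogtt <- get("ogtt_2h")
  for (v in list(fasting, random_g, hba1c, ogtt)) {
    assert_that(all(is.na(v) | v > 0), "measurements must be positive")
  }
  diag <- if ("physician_diagnosis" %in% names(m)) {
    m$physician_diagnosis %in% TRUE
  } else rep(FALSE, nrow(m))
  any_info <- !is.na(fasting) | !is.na(random_g) | !is.na(hba1c) |
    !is.na(ogtt) | diag
  assert_that(all(any_info),
              "at least one measurement or diagnosis flag required")
  ge <- function(x, thr) !is.na(x) & x >= thr
  between <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi

  case <- m$age >= 25 &
    (diag | ge(fasting, 126) | ge(random_g, 200) | ge(hba1c, 6.5))
  pre <- !case & m$age >= 18 &
    (between(fasting, 100, 125) | between(hba1c, 5.7, 6.4) |
       between(ogtt, 140, 199))
  ctrl <- !case & !pre & m$age >= 40
  ifelse(case, "case", ifelse(pre, "prediabetes",
                              ifelse(ctrl, "control", "unclassified")))
}
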