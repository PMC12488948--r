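test_that("effective sample size follows 2*maf*(1-maf)*N*INFO", {
  expect_equal(effective_sample_size(0.5, 100, 1.0), 50.0)
  expect_equal(effective_sample_size(0.01, 1000, 0.5), 9.9)
  expect_equal(effective_sample_size(0.0, 1000, 1.0), 0.0)
  expect_error(effective_sample_size(1.2, 100, 1), "maf")
  expect_error(effective_sample_size(0.5, -1, 1), "n must")
  expect_error(effective_sample_size(0.5, 100, 2), "info")
})

test_that("effective sample size is symmetric in maf and maximal at 0.5", {
  maf <- runif(50, 0, 1)
  expect_equal(effective_sample_size(maf, 500, 0.8),
               effective_sample_size(1 - maf, 500, 0.8))
  expect_true(all(effective_sample_size(maf, 500, 0.8) <=
                    effective_sample_size(0.5, 500, 0.8)))
})

test_that("variant filters keep iff INFO >= 0.4 and effective n >= 30", {
  meta <- data.frame(
    variant_id = paste0("v", 1:4),
    maf = c(0.3, 0.01, 0.5, NA),
    info = c(0.39, 0.9, 1.0, 0.8),
    n = c(1000, 1000, 100, 500)
  )
  out <- filter_variants(meta)
  expect_equal(out$exclude_reason,
               c("low_info", "low_eff_n", "none", "missing_meta"))
  expect_equal(out$kept, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$eff_n[2], 2 * 0.01 * 0.99 * 1000 * 0.9)  # 17.82
  expect_equal(out$eff_n[3], 50)
})

test_that("strand mapping complements alleles on '-' and relocates variants", {
  tab <- data.frame(variant_id = c("a", "b"), chrom = "1", pos = c(10L, 20L),
                    effect_allele = c("A", "A"), other_allele = c("G", "G"),
                    effect_weight = c(0.1, 0.2))
  map <- data.frame(old_chrom = "1", old_pos = c(10L, 20L),
                    new_chrom = "1", new_pos = c(110L, 120L),
                    strand = c("-", "+"))
  out <- apply_strand_mapping(tab, map)
  expect_equal(out$pos, c(110L, 120L))
  expect_equal(out$effect_allele, c("T", "A"))
  expect_equal(out$other_allele, c("C", "G"))
  expect_equal(out$effect_weight, tab$effect_weight)
})

test_that("strand mapping rejects bad alleles and warns on unmapped variants", {
  tab <- data.frame(variant_id = "a", chrom = "1", pos = 10L,
                    effect_allele = "N", other_allele = "G",
                    effect_weight = 0.1)
  map <- data.frame(old_chrom = "1", old_pos = 10L, new_chrom = "1",
                    new_pos = 110L, strand = "-")
  expect_error(apply_strand_mapping(tab, map), "A,C,G,T")

  tab2 <- data.frame(variant_id = c("a", "b"), chrom = "1",
                     pos = c(10L, 99L), effect_allele = "A",
                     other_allele = "G", effect_weight = 0.1)
  expect_warning(out <- apply_strand_mapping(tab2, map), "1 variant")
  expect_equal(nrow(out), 1)
})

test_that("allele matching resolves the four orientations", {
  panel <- data.frame(chrom = "1", pos = c(1L, 2L, 3L, 4L),
                      ref_allele = c("G", "A", "T", "G"),
                      alt_allele = c("A", "G", "C", "A"))
  tab <- data.frame(variant_id = paste0("v", 1:4), chrom = "1",
                    pos = c(1L, 2L, 3L, 4L),
                    effect_allele = c("A", "A", "G", "C"),
                    other_allele = c("G", "G", "A", "T"),
                    effect_weight = 0.1)
  out <- match_alleles(tab, panel)
  # v3: effect G/other A vs ref T/alt C -> complement(G,A)=(C,T) = (alt,ref)
  # v4: effect C/other T vs ref G/alt A -> complement(C,T)=(G,A) = (ref,alt)
  expect_equal(out$orientation, c("direct", "swap", "flip", "swap_flip"))
  expect_true(all(out$exclude_reason == "none"))
})

test_that("palindromic variants follow the ambiguity policy", {
  panel <- data.frame(chrom = "1", pos = 1L, ref_allele = "T",
                      alt_allele = "A")
  tab <- data.frame(variant_id = "v", chrom = "1", pos = 1L,
                    effect_allele = "A", other_allele = "T",
                    effect_weight = 0.1)
  out <- match_alleles(tab, panel)
  expect_equal(out$exclude_reason, "ambiguous")
  expect_true(is.na(out$orientation))
  out2 <- match_alleles(tab, panel, ambiguous_policy = "assume-plus-strand")
  expect_equal(out2$orientation, "direct")
})

test_that("unmatched and conflicting variants are handled", {
  panel <- data.frame(chrom = "1", pos = c(1L, 2L),
                      ref_allele = c("G", "G"), alt_allele = c("A", "C"))
  tab <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
                    pos = c(9L, 2L),
                    effect_allele = c("A", "A"), other_allele = c("G", "G"),
                    effect_weight = 0.1)
  out <- match_alleles(tab, panel)
  expect_equal(out$exclude_reason, c("unmatched", "unmatched"))

  dup_panel <- data.frame(chrom = "1", pos = c(1L, 1L),
                          ref_allele = c("G", "C"), alt_allele = c("A", "T"))
  expect_error(match_alleles(tab, dup_panel), "duplicate")
})

test_that("matching agrees with brute-force enumeration of orientations", {
  set.seed(21)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- function(eff, oth, ref, alt) {
    if (eff == alt && oth == ref) return("direct")
    if (eff == ref && oth == alt) return("swap")
    if (comp[eff] == alt && comp[oth] == ref) return("flip")
    if (comp[eff] == ref && comp[oth] == alt) return("swap_flip")
    NA_character_
  }
  for (i in 1:60) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), c(ref, comp[ref])), 1)
    pair <- sample(c("A", "C", "G", "T"), 2)
    if (pair[1] == pair[2] || comp[pair[1]] == pair[2]) next
    panel <- data.frame(chrom = "1", pos = 1L, ref_allele = ref,
                        alt_allele = alt)
    tab <- data.frame(variant_id = "v", chrom = "1", pos = 1L,
                      effect_allele = pair[1], other_allele = pair[2],
                      effect_weight = 0.1)
    out <- match_alleles(tab, panel)
    want <- oracle(pair[1], pair[2], ref, alt)
    if (is.na(want)) {
      expect_equal(out$exclude_reason, "unmatched")
    } else {
      expect_equal(out$orientation, want)
    }
  }
})

test_that("complementing the panel swaps direct<->flip and swap<->swap_flip", {
  set.seed(33)
  sim <- simulate_cohort(quick_config(n = 50, seed = 12, n_variants = 30))
  tab <- sim$weight_tables$meta
  panel_v <- sim$panel$variants
  a <- match_alleles(tab, panel_v)
  panel_c <- panel_v
  panel_c$ref_allele <- vapply(panel_v$ref_allele,
                               function(x) c(A="T",C="G",G="C",T="A")[[x]], "")
  panel_c$alt_allele <- vapply(panel_v$alt_allele,
                               function(x) c(A="T",C="G",G="C",T="A")[[x]], "")
  b <- match_alleles(tab, panel_c)
  swapmap <- c(direct = "flip", flip = "direct", swap = "swap_flip",
               swap_flip = "swap")
  ok <- a$exclude_reason == "none"
  expect_equal(unname(swapmap[a$orientation[ok]]), b$orientation[ok])
})

test_that("filtering and matching commute on the kept set", {
  sim <- simulate_cohort(quick_config(n = 50, seed = 13, n_variants = 40))
  tab <- sim$weight_tables$meta
  meta <- sim$panel$variants
  meta$info[c(3, 7)] <- 0.1   # force exclusions
  filtered_first <- match_alleles(tab, filter_variants(meta)[
    filter_variants(meta)$kept, ])
  matched_first <- match_alleles(tab, meta)
  f <- filter_variants(meta)
  keep_ids <- meta$variant_id[f$kept]
  a <- filtered_first[filtered_first$exclude_reason == "none", "variant_id"]
  b <- matched_first[matched_first$exclude_reason == "none" &
                       matched_first$variant_id %in% keep_ids, "variant_id"]
  expect_setequal(a, b)
})
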