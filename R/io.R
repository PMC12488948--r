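# Readers and writers for the standard file formats the pipeline consumes
# and emits. All coordinates are 1-based, matching VCF.

#' Read a PGS-Catalog-style scoring file
#'
#' Tab-separated with '#'-prefixed header lines; columns `rsID`,
#' `chr_name`, `chr_position`, `effect_allele`, `other_allele`,
#' `effect_weight` (weights are per-allele log-ORs).
#'
#' @param path scoring file path.
#' @param source_population label stored on the table (default taken from a
#'   `#source_population=` header line if present, else `NA`).
#' @return weight table `data.frame` (`variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `effect_weight`,
#'   `source_population`).
#' @export
read_scoring_file <- function(path, source_population = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(source_population)) {
    m <- grep("^#source_population=", hdr, value = TRUE)
    source_population <- if (length(m)) sub("^#source_population=", "", m[1])
                         else NA_character_
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  need <- c("chr_name", "chr_position", "effect_allele", "other_allele",
            "effect_weight")
  assert_that(all(need %in% names(tab)),
              "scoring file must have columns %s", paste(need, collapse = ", "))
  out <- data.frame(
    variant_id = if ("rsID" %in% names(tab)) tab$rsID else
      paste0(tab$chr_name, ":", tab$chr_position),
    chrom = as.character(tab$chr_name),
    pos = as.integer(tab$chr_position),
    effect_allele = toupper(tab$effect_allele),
    other_allele = toupper(tab$other_allele),
    effect_weight = as.numeric(tab$effect_weight),
    source_population = source_population,
    stringsAsFactors = FALSE
  )
  validate_weight_table(out)
  out
}

#' Write a weight table as a PGS-Catalog-style scoring file
#'
#' @param table weight table `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(table, path) {
  validate_weight_table(table)
  con <- file(path, "w")
  on.exit(close(con))
  src <- unique(table$source_population)
  if (length(src) == 1 && !is.na(src)) {
    writeLines(sprintf("#source_population=%s", src), con)
  }
  out <- data.frame(rsID = table$variant_id, chr_name = table$chrom,
                    chr_position = table$pos,
                    effect_allele = table$effect_allele,
                    other_allele = table$other_allele,
                    effect_weight = table$effect_weight)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a dosage matrix TSV
#'
#' Plain-text dosage exchange format: first columns `variant_id`, `chrom`,
#' `pos`, `ref_allele`, `alt_allele`, `maf`, `info`, `n`, then one column
#' per sample holding the alt-allele dosage.
#'
#' @param path file path.
#' @return a [dosage_panel()].
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "ref_allele", "alt_allele",
                 "maf", "info", "n")
  assert_that(all(meta_cols %in% names(tab)),
              "dosage TSV must start with columns %s",
              paste(meta_cols, collapse = ", "))
  sample_cols <- setdiff(names(tab), meta_cols)
  dos <- t(as.matrix(tab[, sample_cols, drop = FALSE]))
  colnames(dos) <- tab$variant_id
  variants <- tab[, meta_cols]
  variants$chrom <- as.character(variants$chrom)
  dosage_panel(dos, variants)
}

#' @rdname read_dosage_tsv
#' @param panel a [dosage_panel()].
#' @export
write_dosage_tsv <- function(panel, path) {
  tab <- cbind(panel$variants,
               as.data.frame(t(panel$dosages), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dosage panel as a VCF with a DS FORMAT field
#'
#' Minimal uncompressed VCFv4.2 with genotype dosages in the `DS` field
#' (genotypes emitted as `./.` since only dosages are tracked).
#'
#' @param panel a [dosage_panel()].
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- panel$variants
  samples <- rownames(panel$dosages)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    sprintf("##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (j in seq_len(nrow(v))) {
    fields <- c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref_allele[j],
                v$alt_allele[j], ".", "PASS",
                sprintf("INFO=%.4f", v$info[j]), "DS",
                sprintf("%.3f", panel$dosages[, j]))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Uses the `vcfR` package when installed; variant metadata (`maf` from the
#' dosages, `info` from the INFO field when present, `n` = sample count) is
#' reconstructed from the file.
#'
#' @param path VCF path (uncompressed or gzipped).
#' @return a [dosage_panel()].
#' @export
read_dosage_vcf <- function(path) {
  assert_that(requireNamespace("vcfR", quietly = TRUE),
              "read_dosage_vcf() requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_field <- suppressWarnings(
    as.numeric(sub(".*INFO=([0-9.eE+-]+).*", "\\1", fix$INFO))
  )
  dos <- t(ds)
  colnames(dos) <- fix$ID
  maf <- colMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(
    variant_id = fix$ID, chrom = as.character(fix$CHROM),
    pos = as.integer(fix$POS), ref_allele = fix$REF, alt_allele = fix$ALT,
    maf = pmin(maf, 1 - maf), info = info_field, n = nrow(dos),
    stringsAsFactors = FALSE
  )
  dosage_panel(dos, variants)
}

#' Read a coordinate/strand mapping table
#'
#' @param path TSV with columns `old_chrom`, `old_pos`, `new_chrom`,
#'   `new_pos`, `strand`.
#' @return `data.frame` mapping table for [apply_strand_mapping()].
#' @export
read_mapping_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("old_chrom", "old_pos", "new_chrom", "new_pos", "strand")
  assert_that(all(need %in% names(tab)),
              "mapping table must have columns %s", paste(need, collapse = ", "))
  tab
}

#' Read and write phenotype / ICD record TSVs
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname read_phenotype_tsv
#' @param x `data.frame` to write.
#' @export
write_phenotype_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a simulation config as YAML
#'
#' @param path YAML path.
#' @return a [sim_config()].
#' @export
read_sim_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phenome_spec)) {
    y$phenome_spec <- do.call(rbind, lapply(y$phenome_spec, as.data.frame))
  }
  for (nm in c("context_effects", "trait_effects", "n_per_population",
               "alpha")) {
    if (!is.null(y[[nm]])) {
      val <- unlist(y[[nm]])
      # an empty map must stay an explicit NULL, not vanish from the call
      if (is.null(val)) y[nm] <- list(NULL) else y[[nm]] <- val
    }
  }
  do.call(sim_config, y)
}

#' @rdname read_sim_config_yaml
#' @param config a [sim_config()].
#' @export
write_sim_config_yaml <- function(config, path) {
  y <- unclass(config)
  # yaml drops the names of named atomic vectors; write them as maps
  for (nm in c("context_effects", "trait_effects", "n_per_population",
               "alpha")) {
    if (length(y[[nm]])) y[[nm]] <- as.list(y[[nm]])
  }
  y$phenome_spec <- lapply(seq_len(nrow(config$phenome_spec)), function(i) {
    as.list(config$phenome_spec[i, ])
  })
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
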