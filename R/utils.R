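# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_input(fmt, ...)
  invisible(TRUE)
}

VALID_ALLELES <- c("A", "C", "G", "T")

#' Watson-Crick complement of single-nucleotide alleles
#'
#' @param allele character vector of alleles; only A/C/G/T are accepted.
#' @return complemented alleles (A<->T, C<->G).
#' @keywords internal
complement_allele <- function(allele) {
  bad <- !allele %in% VALID_ALLELES
  if (any(bad)) {
    stop_input("allele outside {A,C,G,T}: %s",
               paste(unique(allele[bad]), collapse = ", "))
  }
  unname(c(A = "T", C = "G", G = "C", T = "A")[allele])
}

# A/T and C/G pairs cannot be oriented across strands.
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Deterministic, order-independent 32-bit hash of a character key.
# Used to derive per-cell / per-individual RNG streams from one seed.
stable_hash <- function(key) {
  vapply(key, function(k) {
    bytes <- utf8ToInt(k)
    h <- 19152614L
    for (b in bytes) {
      h <- bitwXor(h, b)
      h <- (h * 16777619) %% 2147483647
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Seed derived from a base seed and a character key, kept below 2^31.
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) + as.numeric(stable_hash(key))) %% 2147483647)
}
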