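## Genotypes are stored as integer bitmasks: gene j (1-based) <-> bit 2^(j-1).
## K is capped at 14 so that full 2^K enumerations stay cheap.

MAX_GENES <- 14L

#' Number of mutated genes in a genotype bitmask
#'
#' @param mask integer vector of genotype bitmasks.
#' @return integer vector of mutation counts.
#' @keywords internal
popcount <- function(mask) {
  n <- integer(length(mask))
  m <- as.integer(mask)
  while (any(m > 0L)) {
    n <- n + (m %% 2L)
    m <- m %/% 2L
  }
  n
}

#' Convert genotype bitmasks to 0/1 strings
#'
#' The first character is gene 1, so `"1010"` has genes 1 and 3 mutated.
#'
#' @param mask integer vector of bitmasks.
#' @param n_genes number of genes K.
#' @return character vector of bitstrings of length `n_genes`.
#' @export
geno_string <- function(mask, n_genes) {
  vapply(as.integer(mask), function(m) {
    paste(ifelse(bitwAnd(m, bitwShiftL(1L, seq_len(n_genes) - 1L)) > 0L,
                 "1", "0"), collapse = "")
  }, character(1))
}

#' Convert 0/1 strings to genotype bitmasks
#'
#' @param s character vector of bitstrings (e.g. `"1010"`).
#' @return integer vector of bitmasks.
#' @export
geno_mask <- function(s) {
  vapply(strsplit(s, ""), function(b) {
    sum(bitwShiftL(1L, which(b == "1") - 1L))
  }, integer(1))
}

#' Genes mutated in a genotype, in index form
#' @keywords internal
mask_genes <- function(mask, n_genes) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_genes) - 1L)) > 0L)
}

default_labels <- function(n_genes) paste0("G", seq_len(n_genes))

check_n_genes <- function(n_genes) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("n_genes must be a single integer >= 1")
  if (n_genes > MAX_GENES)
    stop("n_genes must be <= ", MAX_GENES, " (full genotype enumeration)")
  as.integer(n_genes)
}
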