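#' @importFrom stats rnorm runif rbinom median sd var pnorm setNames complete.cases
#' @importFrom utils read.delim write.table combn head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Standard genetic code, DNA alphabet (Biostrings::GENETIC_CODE uses the same
# table; kept as a direct named lookup so translation is a plain vector index).
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

#' Reverse-complement a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x A character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a DNA coding sequence to protein
#'
#' Translates codon-by-codon with the standard genetic code, stopping at the
#' first stop codon. Used both by the transcript reconstruction machinery and
#' by the synthetic genome generator.
#'
#' @param dna A single DNA string; translation starts at position 1.
#' @param to_first_stop If `TRUE` (default) translation stops at (and
#'   excludes) the first stop codon; otherwise stops are rendered as `*`.
#' @return A single amino-acid string. Attribute `"stop_offset"` carries the
#'   1-based nucleotide offset of the first stop codon, or `NA` if none was
#'   seen before the end of the sequence.
#' @export
translate_dna <- function(dna, to_first_stop = TRUE) {
  stopifnot(is.character(dna), length(dna) == 1L)
  n_codon <- nchar(dna) %/% 3L
  if (n_codon == 0L) {
    out <- ""
    attr(out, "stop_offset") <- NA_integer_
    return(out)
  }
  starts <- seq(1L, by = 3L, length.out = n_codon)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(codon_table()[codons])
  aa[is.na(aa)] <- "X"
  stop_idx <- which(aa == "*")
  if (to_first_stop && length(stop_idx) > 0L) {
    first <- stop_idx[1L]
    out <- paste(aa[seq_len(first - 1L)], collapse = "")
    attr(out, "stop_offset") <- starts[first]
  } else {
    out <- paste(aa, collapse = "")
    attr(out, "stop_offset") <- if (length(stop_idx)) starts[stop_idx[1L]] else NA_integer_
  }
  out
}

# Reverse map: one arbitrary (but fixed) codon per amino acid, plus the full
# synonymous sets for randomized encodings.
aa_codon_sets <- function() {
  ct <- codon_table()
  split(names(ct), ct)
}

# Encode an amino-acid string as DNA, drawing synonymous codons at random
# (uses the current RNG state; callers seed).
encode_peptide <- function(peptide) {
  sets <- aa_codon_sets()
  aa <- strsplit(peptide, "")[[1]]
  bad <- setdiff(aa, setdiff(names(sets), "*"))
  if (length(bad) > 0L) {
    stop("peptide contains unencodable residues: ", paste(unique(bad), collapse = ","))
  }
  paste(vapply(aa, function(a) {
    s <- sets[[a]]
    s[sample.int(length(s), 1L)]
  }, character(1)), collapse = "")
}

# Random DNA of length n (uses current RNG state).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Random protein with a leading methionine (no stops).
random_protein <- function(n_res) {
  aas <- setdiff(unique(unname(codon_table())), "*")
  body <- sample(aas, n_res - 1L, replace = TRUE)
  paste(c("M", body), collapse = "")
}

gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
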