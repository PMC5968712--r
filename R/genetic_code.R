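#' Genetic code tables
#'
#' Returns a genetic code as a named character vector mapping each of the 64
#' DNA codons to a one-letter amino acid, with `"*"` marking stop codons.
#' The standard nuclear code (table 1) is the default and is appropriate for
#' plant nuclear transcripts; the table is taken from
#' [Biostrings::getGeneticCode()].
#'
#' @param table_id NCBI genetic-code table identifier (default `"1"`).
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(table_id = "1") {
  code <- Biostrings::getGeneticCode(as.character(table_id))
  # Biostrings uses RNA-style names for some tables; normalize to DNA codons
  names(code) <- chartr("U", "T", names(code))
  stopifnot(length(code) == 64L)
  code
}

#' Sense codons of a genetic code
#'
#' @param code genetic code from [genetic_code()].
#' @return Character vector of non-stop codons (61 for the standard code).
#' @export
sense_codons <- function(code = genetic_code()) {
  names(code)[code != "*"]
}

#' Split a nucleotide string into codons
#'
#' @param x single nucleotide string, length divisible by 3.
#' @return Character vector of codon triplets.
#' @export
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not divisible by 3")
  }
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' One residue per codon. Codons containing characters outside `{A,C,G,T}`
#' (ambiguity codes, `N`, or gaps) translate to `X`; such codons are also
#' excluded from all downstream substitution counting. An internal stop codon
#' is an error because the coding sequences handled here are expected to be
#' stop-trimmed open reading frames.
#'
#' @param cds nucleotide string (upper case), length divisible by 3.
#' @param code genetic code from [genetic_code()].
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  cod <- split_codons(toupper(cds))
  aa <- unname(code[cod])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    stop("internal stop codon '", cod[stops[1L]], "' at codon ", stops[1L])
  }
  paste(aa, collapse = "")
}

#' Trim a single terminal stop codon from a CDS
#'
#' @inheritParams translate_cds
#' @return The CDS without its final codon when that codon is a stop,
#'   otherwise unchanged.
#' @export
trim_terminal_stop <- function(cds, code = genetic_code()) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not divisible by 3")
  if (n >= 3L) {
    last <- substr(cds, n - 2L, n)
    if (!is.na(code[last]) && code[last] == "*") {
      return(substr(cds, 1L, n - 3L))
    }
  }
  cds
}
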