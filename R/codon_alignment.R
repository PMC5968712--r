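#' Codon alignments
#'
#' A codon alignment is stored as a named character vector of equal-length,
#' gapped, upper-case nucleotide strings whose length is divisible by 3 and
#' whose gaps occur as whole codons (`"---"`) on codon boundaries. This is
#' the substrate of all substitution-rate estimation in the package.
#'
#' @param seqs named character vector of gapped sequences.
#' @return The validated vector with class `codon_alignment`.
#' @export
codon_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == "")) {
    stop("codon alignment rows must carry unique non-empty ids")
  }
  seqs <- toupper(unlist(seqs))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("alignment rows differ in length")
  if (len %% 3L != 0L) stop("alignment length ", len, " is not divisible by 3")
  for (id in names(seqs)) {
    cod <- split_codons(seqs[[id]])
    bad <- grepl("-", cod) & cod != "---"
    if (any(bad)) {
      stop("row '", id, "': gap not aligned to a codon boundary at codon ",
           which(bad)[1L])
    }
  }
  structure(seqs, class = "codon_alignment")
}

#' Remove gaps from an aligned sequence
#'
#' @param x gapped sequence string.
#' @return Ungapped sequence.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Alignment rows as a codon matrix
#'
#' @param aln codon alignment.
#' @return Character matrix, rows = sequences, columns = codon positions.
#' @keywords internal
codon_matrix <- function(aln) {
  m <- t(vapply(unclass(aln), split_codons,
                character(nchar(aln[[1L]]) / 3L)))
  rownames(m) <- names(aln)
  m
}

#' Drop codon columns unusable for substitution counting
#'
#' Complete-deletion column filter: a codon column is kept only when every
#' row holds an unambiguous sense codon (no gap, no non-ACGT character, no
#' stop). This mirrors the usual "cleandata" treatment applied before
#' counting-based and likelihood-based rate estimation.
#'
#' @param aln codon alignment.
#' @param code genetic code.
#' @return Filtered `codon_alignment` (possibly zero columns).
#' @export
clean_codon_columns <- function(aln, code = genetic_code()) {
  m <- codon_matrix(codon_alignment(aln))
  ok_row <- function(cod) {
    aa <- code[cod]
    !is.na(aa) & aa != "*"
  }
  keep <- apply(m, 2L, function(col) all(ok_row(col)))
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (sum(keep) == 0L) out <- stats::setNames(rep("", nrow(m)), rownames(m))
  codon_alignment(out)
}
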