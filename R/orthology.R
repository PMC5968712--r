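#' Global protein alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()].
#' The defaults (BLOSUM62, gap open 10, gap extend 0.5) approximate
#' protein-search scoring at desk scale so that ortholog detection does not
#' require an external search binary; precomputed hit tables can be
#' supplied to [rbh_pairs()] instead.
#'
#' @param a,b protein sequences (plain strings).
#' @param substitution_matrix scoring matrix name or matrix
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend positive penalties.
#' @return List with `score`, `aligned_a`, `aligned_b`, `pident` (percent
#'   identity over aligned columns).
#' @export
align_proteins_global <- function(a, b, substitution_matrix = "BLOSUM62",
                                  gap_open = 10, gap_extend = 0.5) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ra <- as.character(Biostrings::alignedPattern(pa))
  rb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ra, "")[[1L]]
  cb <- strsplit(rb, "")[[1L]]
  list(score = Biostrings::score(pa), aligned_a = unname(ra),
       aligned_b = unname(rb),
       pident = 100 * sum(ca == cb & ca != "-") / length(ca))
}

# all-vs-all alignment scores between two proteomes, as a hit table
internal_hits <- function(proteome_a, proteome_b, ...) {
  rows <- list()
  for (qa in names(proteome_a)) {
    for (sb in names(proteome_b)) {
      al <- align_proteins_global(proteome_a[[qa]], proteome_b[[sb]], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        query = qa, subject = sb, pident = al$pident,
        evalue = NA_real_, bitscore = al$score, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Reciprocal-best-hit ortholog pairs
#'
#' Gene x of species A is paired with gene y of species B iff y is the
#' unique best-scoring hit of x and x the unique best-scoring hit of y.
#' Best-hit ties exclude the gene from pairing (with a warning), since a
#' tied best hit is not evidence of one-to-one orthology.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences (used for internal scoring when `hits` is `NULL`; only the
#'   names are needed otherwise).
#' @param hits optional hit table(s) from [read_blast_tab()]: either one
#'   table containing both directions or a list of two (A vs B, B vs A).
#'   When omitted, scores come from [align_proteins_global()], which is
#'   symmetric, so one direction suffices.
#' @param max_evalue optional e-value filter applied to `hits`.
#' @param min_bitscore optional bitscore filter applied to `hits`.
#' @return `data.frame` of ortholog pairs: `gene_a`, `gene_b`, `score`,
#'   `pident`.
#' @export
rbh_pairs <- function(proteome_a, proteome_b, hits = NULL,
                      max_evalue = NULL, min_bitscore = NULL) {
  if (is.null(hits)) {
    hits <- internal_hits(proteome_a, proteome_b)
  } else if (is.list(hits) && !is.data.frame(hits)) {
    hits <- do.call(rbind, lapply(hits, function(h) {
      stopifnot(is.data.frame(h))
      h
    }))
  }
  if (!is.null(max_evalue)) {
    hits <- hits[!is.na(hits$evalue) & hits$evalue <= max_evalue, ,
                 drop = FALSE]
  }
  if (!is.null(min_bitscore)) {
    hits <- hits[hits$bitscore >= min_bitscore, , drop = FALSE]
  }
  ids_a <- names(proteome_a)
  ids_b <- names(proteome_b)
  # orient every hit as (gene in A, gene in B); keep best score per pair
  fwd <- hits[hits$query %in% ids_a & hits$subject %in% ids_b,
              c("query", "subject", "bitscore", "pident"), drop = FALSE]
  rev <- hits[hits$query %in% ids_b & hits$subject %in% ids_a,
              c("subject", "query", "bitscore", "pident"), drop = FALSE]
  names(fwd) <- names(rev) <- c("gene_a", "gene_b", "score", "pident")
  ab <- rbind(fwd, rev)
  if (nrow(ab) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), pident = numeric(0)))
  }
  ab <- ab[order(-ab$score), , drop = FALSE]
  ab <- ab[!duplicated(ab[, c("gene_a", "gene_b")]), , drop = FALSE]
  best_unique <- function(keys, scores, partners) {
    out <- list()
    for (k in unique(keys)) {
      idx <- which(keys == k)
      top <- max(scores[idx])
      winners <- idx[scores[idx] == top]
      if (length(winners) == 1L) {
        out[[k]] <- partners[winners]
      } else {
        warning("tied best hit for '", k, "'; excluded from pairing")
      }
    }
    out
  }
  best_a <- best_unique(ab$gene_a, ab$score, ab$gene_b)
  best_b <- best_unique(ab$gene_b, ab$score, ab$gene_a)
  pairs <- list()
  for (ga in names(best_a)) {
    gb <- best_a[[ga]]
    if (!is.null(best_b[[gb]]) && best_b[[gb]] == ga) {
      row <- ab[ab$gene_a == ga & ab$gene_b == gb, , drop = FALSE][1L, ]
      pairs[[length(pairs) + 1L]] <- row
    }
  }
  out <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               score = numeric(0), pident = numeric(0))
  rownames(out) <- NULL
  out
}

#' Single-copy ortholog groups across k species
#'
#' Maximal reciprocal-best-hit cliques: a group is one gene per species
#' such that every cross-species pair within the group is an RBH pair.
#' Because each gene has at most one RBH partner per other species, every
#' gene belongs to at most one group.
#'
#' @param pair_list named list of RBH tables from [rbh_pairs()]; names are
#'   `"A:B"` species-pair labels and each table must carry `gene_a`
#'   (species before the colon) and `gene_b` columns.
#' @param species character vector of the k species in output column
#'   order.
#' @return `data.frame` with one column per species and one row per
#'   single-copy group.
#' @export
single_copy_groups <- function(pair_list, species) {
  k <- length(species)
  if (k < 2L) stop("at least two species are required")
  need <- utils::combn(species, 2L)
  lookup <- list()
  for (nm in names(pair_list)) {
    sp <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (length(sp) != 2L) stop("pair name '", nm, "' is not 'A:B'")
    tab <- pair_list[[nm]]
    lookup[[paste(sp[1L], sp[2L], sep = ":")]] <-
      stats::setNames(tab$gene_b, tab$gene_a)
    lookup[[paste(sp[2L], sp[1L], sep = ":")]] <-
      stats::setNames(tab$gene_a, tab$gene_b)
  }
  for (i in seq_len(ncol(need))) {
    key <- paste(need[1L, i], need[2L, i], sep = ":")
    if (is.null(lookup[[key]])) {
      stop("missing RBH table for species pair ", key)
    }
  }
  anchor <- species[1L]
  anchor_genes <- names(lookup[[paste(anchor, species[2L], sep = ":")]])
  rows <- list()
  for (g in anchor_genes) {
    members <- stats::setNames(c(g, rep(NA_character_, k - 1L)), species)
    for (sp in species[-1L]) {
      members[[sp]] <- lookup[[paste(anchor, sp, sep = ":")]][g]
      if (is.na(members[[sp]])) break
    }
    if (any(is.na(members))) next
    ok <- TRUE
    for (i in seq_len(ncol(need))) {
      a <- need[1L, i]; b <- need[2L, i]
      partner <- lookup[[paste(a, b, sep = ":")]][members[[a]]]
      if (is.na(partner) || partner != members[[b]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) rows[[length(rows) + 1L]] <- as.data.frame(as.list(members),
                                                       stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(character(0), 0L, k)), species)
  rownames(out) <- NULL
  out
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned residue column becomes the corresponding codon of the
#' (unaligned) coding sequence; residue gaps expand to `"---"`. The
#' translation of each CDS must reproduce the ungapped protein row exactly.
#'
#' @param protein_alignment named character vector of equal-length gapped
#'   protein rows.
#' @param cds named character vector of coding sequences covering the same
#'   ids (stop-trimmed, length 3x the ungapped protein length).
#' @param code genetic code.
#' @return [codon_alignment()] mirroring the residue columns.
#' @export
backtranslate_alignment <- function(protein_alignment, cds,
                                    code = genetic_code()) {
  lens <- unique(nchar(protein_alignment))
  if (length(lens) != 1L) stop("protein rows differ in length")
  rows <- character(0)
  for (id in names(protein_alignment)) {
    if (!id %in% names(cds)) stop("no coding sequence for '", id, "'")
    res <- strsplit(protein_alignment[[id]], "")[[1L]]
    cod <- split_codons(toupper(cds[[id]]))
    prot <- strsplit(translate_cds(cds[[id]], code), "")[[1L]]
    ungapped <- res[res != "-"]
    if (length(ungapped) != length(prot)) {
      stop("'", id, "': protein row has ", length(ungapped),
           " residues but the CDS translates to ", length(prot))
    }
    mism <- which(ungapped != prot)
    if (length(mism) > 0L) {
      stop("'", id, "': translation mismatch at residue ", mism[1L],
           " ('", ungapped[mism[1L]], "' vs '", prot[mism[1L]], "')")
    }
    out <- character(length(res))
    out[res == "-"] <- "---"
    out[res != "-"] <- cod
    rows[[id]] <- paste(out, collapse = "")
  }
  codon_alignment(rows)
}
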