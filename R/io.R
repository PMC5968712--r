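#' Read sequences from a FASTA file
#'
#' @param path FASTA file. Records may be line-wrapped.
#' @return Named character vector of sequences (ids are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id '", ids[duplicated(ids)][1L], "' in ", path)
  }
  stats::setNames(as.character(set), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop("sequences must be named")
  set <- Biostrings::BStringSet(unlist(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write newick trees
#'
#' Trees are `ape` `phylo` objects. Foreground branches for branch-site
#' scans follow the usual codon-model convention of a `#1` suffix on the
#' label of the node subtending the branch (see [mark_foreground()]), so
#' externally prepared trees are reusable as-is.
#'
#' @param path newick file containing a single tree.
#' @return `phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in newick file ", path)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse newick file ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in ", path)
  tree
}

#' @rdname read_newick
#' @param tree `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Mark or locate the foreground branch of a tree
#'
#' The branch leading to the named tip is flagged by appending `#1` to the
#' tip label, the convention used by codon-model software for foreground
#' lineages.
#'
#' @param tree `phylo` tree.
#' @param tip unsuffixed tip label.
#' @return `mark_foreground()`: the relabelled tree. `foreground_tip()`: the
#'   unsuffixed label of the marked tip, or `NA` if none is marked.
#' @export
mark_foreground <- function(tree, tip) {
  hit <- which(strip_foreground_labels(tree$tip.label) == tip)
  if (length(hit) != 1L) stop("tip '", tip, "' not found in tree")
  tree$tip.label <- strip_foreground_labels(tree$tip.label)
  tree$tip.label[hit] <- paste0(tip, "#1")
  tree
}

#' @rdname mark_foreground
#' @export
foreground_tip <- function(tree) {
  hit <- grep("#\\d+$", tree$tip.label)
  if (length(hit) == 0L) return(NA_character_)
  strip_foreground_labels(tree$tip.label[hit[1L]])
}

strip_foreground_labels <- function(x) sub("#\\d+$", "", x)

#' Read a two-column gene-to-category annotation table
#'
#' @param path TSV with columns gene id and category id (GO term, pathway,
#'   ...), no header. A gene may appear on several rows.
#' @return `data.frame` with columns `gene` and `category`; duplicated rows
#'   are collapsed.
#' @export
read_annotation_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty annotation file ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L | vapply(parts, function(p)
    !nzchar(p[1L]) || !nzchar(p[2L]), logical(1L)))
  if (length(bad) > 0L) {
    stop("malformed annotation row at line ", bad[1L], " of ", path)
  }
  ann <- data.frame(
    gene = vapply(parts, `[`, character(1L), 1L),
    category = vapply(parts, `[`, character(1L), 2L),
    stringsAsFactors = FALSE
  )
  unique(ann)
}

#' Write an annotation table
#' @param annotation data.frame with columns `gene`, `category`.
#' @param path output path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation[, c("gene", "category")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples count matrix
#'
#' @param path TSV with a header row of sample ids and gene ids in the
#'   first column. Counts must be non-negative integers.
#' @return Integer matrix (genes x samples) with a `lib.sizes` attribute
#'   defaulting to the column sums.
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric count values in ", path)
  if (any(is.na(m))) stop("missing count values in ", path)
  if (any(m < 0)) stop("negative count value in ", path)
  if (any(m != round(m))) stop("non-integer count value in ", path)
  storage.mode(m) <- "integer"
  attr(m, "lib.sizes") <- colSums(m)
  m
}

#' Write a count matrix
#' @param counts genes-by-samples matrix.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tabular similarity hits (12-column outfmt-6 dialect)
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, e-value, bitscore. Only the best
#' (highest bitscore) hit is retained per (query, subject) pair.
#'
#' @param path tabular hits file, no header.
#' @return `data.frame` with columns `query`, `subject`, `pident`,
#'   `evalue`, `bitscore`, one row per pair.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad) > 0L) stop("malformed hit row at line ", bad[1L], " of ", path)
  hits <- data.frame(
    query = vapply(parts, `[`, character(1L), 1L),
    subject = vapply(parts, `[`, character(1L), 2L),
    pident = as.numeric(vapply(parts, `[`, character(1L), 3L)),
    evalue = as.numeric(vapply(parts, `[`, character(1L), 11L)),
    bitscore = as.numeric(vapply(parts, `[`, character(1L), 12L)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(hits$bitscore))) stop("non-numeric bitscore in ", path)
  hits <- hits[order(-hits$bitscore), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("query", "subject")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
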