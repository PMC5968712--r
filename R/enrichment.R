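#' Fisher-exact category enrichment of a gene set
#'
#' For every category, builds the 2x2 table of (in/out of the study set) x
#' (in/out of the category) over the population and applies the one-tailed
#' (over-representation) Fisher exact test with Benjamini-Hochberg
#' correction across categories, the usual convention for gene-set
#' enrichment.
#' The population defaults to all annotated genes, since comparisons of
#' annotated category contents are only meaningful within the annotated
#' universe; pass `population` explicitly to widen it.
#'
#' @param study character vector of study gene ids (e.g. DEGs or PSGs).
#' @param annotation data.frame with columns `gene`, `category`.
#' @param population population gene ids; default: all annotated genes.
#'   The study set must be a subset.
#' @param fdr_cutoff enrichment threshold on the adjusted p (default 0.05).
#' @return `data.frame` with one row per category: `category`,
#'   `study_count`, `study_size`, `pop_count`, `pop_size`, `odds`, `p`,
#'   `q`, `enriched` (q below cutoff and odds above 1).
#' @export
fisher_enrichment <- function(study, annotation, population = NULL,
                              fdr_cutoff = 0.05) {
  if (length(study) == 0L) stop("empty study set")
  if (is.null(population)) population <- unique(annotation$gene)
  population <- unique(population)
  study <- unique(study)
  if (!all(study %in% population)) {
    stop("study set must be a subset of the population")
  }
  ann <- annotation[annotation$gene %in% population, , drop = FALSE]
  cats <- split(ann$gene, ann$category)
  n_pop <- length(population)
  n_study <- length(study)
  rows <- lapply(names(cats), function(cat) {
    in_cat <- unique(cats[[cat]])
    a <- sum(study %in% in_cat)
    b <- n_study - a
    c_ <- length(in_cat) - a
    d <- n_pop - n_study - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                             alternative = "greater")
    data.frame(category = cat, study_count = a, study_size = n_study,
               pop_count = length(in_cat), pop_size = n_pop,
               odds = if (b == 0 || c_ == 0) {
                 if (a == 0 || d == 0) NA_real_ else Inf
               } else (a * d) / (b * c_),
               p = min(ft$p.value, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$enriched <- out$q < fdr_cutoff & !is.na(out$odds) & out$odds > 1
  rownames(out) <- NULL
  out
}

#' Per-category content comparison between two species
#'
#' For every category annotated in either species, builds the 2x2 table
#' (species x in/out of category) with the species' total annotated gene
#' counts as margins, applies the two-sided Fisher test, and corrects with
#' BH-FDR. The direction records which species over-represents the
#' category.
#'
#' @param annotation_a,annotation_b per-species annotation data.frames
#'   (columns `gene`, `category`).
#' @param total_a,total_b gene totals forming the margins; default: the
#'   number of annotated genes per species.
#' @param fdr_cutoff significance threshold (default 0.05).
#' @return `data.frame` with `category`, `count_a`, `total_a`, `count_b`,
#'   `total_b`, `direction` (`"a"`, `"b"` or `"none"` for equal
#'   proportions), `p`, `q`, `significant`.
#' @export
compare_species_categories <- function(annotation_a, annotation_b,
                                       total_a = NULL, total_b = NULL,
                                       fdr_cutoff = 0.05) {
  if (is.null(total_a)) total_a <- length(unique(annotation_a$gene))
  if (is.null(total_b)) total_b <- length(unique(annotation_b$gene))
  count_in <- function(ann) {
    vapply(split(ann$gene, ann$category), function(g) length(unique(g)),
           integer(1L))
  }
  ca <- count_in(annotation_a)
  cb <- count_in(annotation_b)
  cats <- sort(union(names(ca), names(cb)))
  rows <- lapply(cats, function(cat) {
    a <- if (cat %in% names(ca)) ca[[cat]] else 0L
    b <- if (cat %in% names(cb)) cb[[cat]] else 0L
    ft <- stats::fisher.test(matrix(c(a, total_a - a, b, total_b - b),
                                    2L, byrow = TRUE))
    pa <- a / total_a
    pb <- b / total_b
    data.frame(category = cat, count_a = a, total_a = total_a,
               count_b = b, total_b = total_b,
               direction = if (pa > pb) "a" else if (pb > pa) "b" else "none",
               p = min(ft$p.value, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_cutoff
  rownames(out) <- NULL
  out
}
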