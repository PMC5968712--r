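test_that("global protein alignment matches hand-scored examples", {
  # identical sequences: ungapped self-alignment scores the diagonal sum
  data(BLOSUM62, package = "Biostrings", envir = environment())
  seqs <- "MKVLAWQTSD"
  al <- align_proteins_global(seqs, seqs)
  diag_sum <- sum(BLOSUM62[cbind(strsplit(seqs, "")[[1]],
                                 strsplit(seqs, "")[[1]])])
  expect_equal(al$score, diag_sum)
  expect_equal(al$pident, 100)
  # single-residue deletion: one gap of length 1
  al2 <- align_proteins_global("ACD", "AD")
  expect_equal(al2$score,
               BLOSUM62["A", "A"] + BLOSUM62["D", "D"] - (10 + 0.5))
  expect_equal(al2$aligned_b, "A-D")
  expect_error(align_proteins_global("", "AD"), "empty")
})

test_that("alignment score equals the exhaustive-enumeration oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(40)
  aas <- rownames(BLOSUM62)[1:20]
  for (i in 1:8) {
    a <- paste(sample(aas, sample(3:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:5, 1), replace = TRUE), collapse = "")
    expect_equal(align_proteins_global(a, b)$score,
                 oracle_align_score(a, b, BLOSUM62),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric in argument order", {
  set.seed(41)
  aas <- c("A", "C", "D", "E", "K", "L", "W")
  for (i in 1:5) {
    a <- paste(sample(aas, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 8, replace = TRUE), collapse = "")
    expect_equal(align_proteins_global(a, b)$score,
                 align_proteins_global(b, a)$score)
  }
})

make_hits <- function(score_mat, ids_a, ids_b) {
  rows <- list()
  for (i in seq_along(ids_a)) {
    for (j in seq_along(ids_b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        query = ids_a[i], subject = ids_b[j], pident = 90,
        evalue = 1e-30, bitscore = score_mat[i, j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("reciprocal best hits follow mutual unique-best rule", {
  ids_a <- c("a1", "a2", "a3")
  ids_b <- c("b1", "b2", "b3")
  pa <- setNames(rep("M", 3), ids_a)
  pb <- setNames(rep("M", 3), ids_b)
  # enumerating best hits in both directions pairs (a1,b1),(a2,b2),(a3,b3)
  m <- matrix(c(9, 1, 1, 1, 8, 7, 1, 7, 8), 3, byrow = TRUE)
  pairs <- rbh_pairs(pa, pb, hits = make_hits(m, ids_a, ids_b))
  expect_equal(pairs[order(pairs$gene_a), c("gene_a", "gene_b")],
               data.frame(gene_a = ids_a, gene_b = ids_b),
               ignore_attr = TRUE)
  # a tie for the best hit excludes the gene
  m2 <- matrix(c(9, 1, 1, 1, 8, 8, 1, 2, 3), 3, byrow = TRUE)
  expect_warning(
    pairs2 <- rbh_pairs(pa, pb, hits = make_hits(m2, ids_a, ids_b)),
    "tied")
  expect_false("a2" %in% pairs2$gene_a)
})

test_that("identical proteomes pair every gene with its twin", {
  set.seed(42)
  prots <- setNames(
    sapply(1:4, function(i) translate_cds(random_cds(25))),
    paste0("g", 1:4))
  pa <- setNames(prots, paste0("A_", names(prots)))
  pb <- setNames(prots, paste0("B_", names(prots)))
  pairs <- rbh_pairs(pa, pb)
  expect_equal(nrow(pairs), 4L)
  expect_equal(sub("^A_", "", pairs$gene_a), sub("^B_", "", pairs$gene_b))
})

test_that("rbh is symmetric under swapping the two species", {
  set.seed(43)
  pa <- setNames(sapply(1:3, function(i) translate_cds(random_cds(20))),
                 paste0("a", 1:3))
  pb <- setNames(sapply(1:3, function(i) translate_cds(random_cds(20))),
                 paste0("b", 1:3))
  # random short proteins can tie; tie handling has its own test above
  ab <- suppressWarnings(rbh_pairs(pa, pb))
  ba <- suppressWarnings(rbh_pairs(pb, pa))
  expect_equal(ab[order(ab$gene_a), c("gene_a", "gene_b")],
               setNames(ba[order(ba$gene_b), c("gene_b", "gene_a")],
                        c("gene_a", "gene_b")),
               ignore_attr = TRUE)
})

test_that("single-copy groups are exactly the RBH cliques", {
  pair_tab <- function(a, b) {
    data.frame(gene_a = a, gene_b = b, score = 100, pident = 95,
               stringsAsFactors = FALSE)
  }
  pl <- list(
    "A:B" = pair_tab(c("a1", "a2"), c("b1", "b2")),
    "A:C" = pair_tab(c("a1", "a2"), c("c1", "c2")),
    "B:C" = pair_tab(c("b1"), c("c1"))   # b2-c2 edge missing
  )
  groups <- single_copy_groups(pl, c("A", "B", "C"))
  expect_equal(nrow(groups), 1L)
  expect_equal(unlist(groups[1, ]), c(A = "a1", B = "b1", C = "c1"))
  expect_error(single_copy_groups(pl[1:2], c("A", "B", "C")), "missing")
})

test_that("simulated one-gene-per-species families give one group each", {
  sim <- simulate_alignment(sim_config(congener_tree(), n_genes = 3,
                                       codons_per_gene = 60, seed = 44))
  species <- c("Mmicrantha", "Mcordata", "Mcordifolia")
  prot <- function(sp) {
    setNames(
      sapply(names(sim$alignments), function(g)
        translate_cds(ungap(sim$alignments[[g]][[sp]]))),
      paste0(sp, ".", names(sim$alignments)))
  }
  prots <- lapply(setNames(species, species), prot)
  pl <- list()
  for (i in 1:2) for (j in (i + 1):3) {
    pl[[paste(species[i], species[j], sep = ":")]] <-
      rbh_pairs(prots[[i]], prots[[j]])
  }
  groups <- single_copy_groups(pl, species)
  expect_equal(nrow(groups), 3L)
  # each group holds the same underlying gene in every species
  for (r in seq_len(nrow(groups))) {
    genes <- sub("^[^.]+\\.", "", unlist(groups[r, ]))
    expect_length(unique(genes), 1L)
  }
})

test_that("back-translation expands gaps and validates the CDS", {
  aln <- backtranslate_alignment(c(x = "MK", y = "MK"),
                                 c(x = "ATGAAA", y = "ATGAAG"))
  expect_equal(unclass(aln), c(x = "ATGAAA", y = "ATGAAG"),
               ignore_attr = TRUE)
  aln2 <- backtranslate_alignment(c(x = "M-K", y = "MQK"),
                                  c(x = "ATGAAA", y = "ATGCAAAAA"))
  expect_equal(aln2[["x"]], "ATG---AAA")
  expect_error(
    backtranslate_alignment(c(x = "MW"), c(x = "ATGAAA")),
    "residue 2")
})

test_that("back-translation then ungapping recovers each CDS", {
  set.seed(45)
  cds <- c(x = random_cds(12), y = random_cds(10))
  prots <- vapply(cds, translate_cds, character(1))
  al <- align_proteins_global(prots[["x"]], prots[["y"]])
  aln <- backtranslate_alignment(c(x = al$aligned_a, y = al$aligned_b), cds)
  expect_equal(ungap(aln[["x"]]), unname(cds[["x"]]))
  expect_equal(ungap(aln[["y"]]), unname(cds[["y"]]))
})
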