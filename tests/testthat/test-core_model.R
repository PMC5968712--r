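test_that("translation maps codons to residues and flags internal stops", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_error(translate_cds("ATGTAA"), "codon 2")
  expect_error(translate_cds("ATGA"), "not divisible by 3")
  expect_equal(translate_cds("ATGNNAAAA"), "MXK")
  expect_equal(trim_terminal_stop("ATGAAATAA"), "ATGAAA")
  expect_equal(trim_terminal_stop("ATGAAA"), "ATGAAA")
})

test_that("translating a random CDS is consistent with the code table", {
  set.seed(1)
  code <- genetic_code()
  for (rep in 1:5) {
    cds <- random_cds(30)
    prot <- translate_cds(cds)
    cod <- split_codons(cds)
    res <- strsplit(prot, "")[[1L]]
    # every codon belongs to the degeneracy class of its residue
    for (i in seq_along(cod)) {
      expect_true(cod[i] %in% names(code)[code == res[i]])
    }
  }
})

test_that("translation commutes with codon-boundary slicing", {
  set.seed(2)
  x <- random_cds(10)
  y <- random_cds(7)
  expect_equal(translate_cds(paste0(x, y)),
               paste0(translate_cds(x), translate_cds(y)))
})

test_that("FASTA reading handles wrapping, ids, and duplicates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 description text", "ACGT"), f)
  expect_equal(read_fasta(f), c(g1 = "ACGT"))
  writeLines(c(">g1", "ACG", "TAC", ">g2", "GG"), f)
  expect_equal(read_fasta(f), c(g1 = "ACGTAC", g2 = "GG"))
  writeLines(c(">g1", "AC", ">g1", "GT"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("FASTA write/read round-trips simulator output", {
  sim <- simulate_alignment(sim_config(two_tip_tree(0.2), n_genes = 1,
                                       codons_per_gene = 40, seed = 5))
  seqs <- unclass(sim$alignments$gene1)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
})

test_that("newick reading parses topologies and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:0.1,B:0.1):0.05,C:0.2);", f)
  tr <- read_newick(f)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(sort(tr$edge.length), c(0.05, 0.1, 0.1, 0.2))
  writeLines("(A,B,C);", f)
  tr2 <- read_newick(f)
  expect_equal(length(tr2$tip.label), 3L)
  expect_null(tr2$edge.length)
  writeLines("((A:0.1,B:0.1:0.05,C:0.2);", f)
  expect_error(read_newick(f), "unbalanced")
})

test_that("newick round-trip is lossless on random trees", {
  set.seed(3)
  f <- withr::local_tempfile(fileext = ".nwk")
  for (i in 1:10) {
    tr <- ape::rtree(sample(3:8, 1))
    write_newick(tr, f)
    back <- read_newick(f)
    expect_equal(ape::write.tree(back), ape::write.tree(tr))
  }
})

test_that("foreground branch marks survive the newick round-trip", {
  tr <- mark_foreground(congener_tree(), "Mmicrantha")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_equal(foreground_tip(read_newick(f)), "Mmicrantha")
})

test_that("annotation reader validates rows and collapses duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tGO:0009538", "g1\tGO:0009538", "g2\tGO:0000988"), f)
  ann <- read_annotation_tsv(f)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$category[ann$gene == "g1"], "GO:0009538")
  writeLines(c("g1\tGO:0009538", "brokenrow"), f)
  expect_error(read_annotation_tsv(f), "line 2")
})

test_that("count reader enforces non-negative integers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t3\t0", "g2\t10\t7"), f)
  m <- read_counts_tsv(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(attr(m, "lib.sizes"), c(s1 = 13, s2 = 7))
  writeLines(c("gene\ts1\ts2", "g1\t-3\t0"), f)
  expect_error(read_counts_tsv(f), "negative")
})

test_that("hit-table reader keeps the best bitscore per pair", {
  f <- withr::local_tempfile(fileext = ".tsv")
  row <- function(q, s, bits) {
    paste(q, s, 95, 100, 5, 0, 1, 100, 1, 100, 1e-50, bits, sep = "\t")
  }
  writeLines(c(row("q1", "s1", 200), row("q1", "s1", 250),
               row("q1", "s2", 90)), f)
  hits <- read_blast_tab(f)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$bitscore[hits$subject == "s1"], 250)
  writeLines("q1\ts1\tshort", f)
  expect_error(read_blast_tab(f), "line 1")
})

test_that("codon alignment enforces codon-boundary gaps and cleaning", {
  expect_error(codon_alignment(c(a = "ATG-AA", b = "ATGAAA")), "boundary")
  aln <- codon_alignment(c(a = "ATG---AAA", b = "ATGCCCAAA"))
  cleaned <- clean_codon_columns(aln)
  expect_equal(unclass(cleaned), c(a = "ATGAAA", b = "ATGAAA"),
               ignore_attr = TRUE)
  # ambiguous codons are dropped too
  aln2 <- codon_alignment(c(a = "ATGNNNAAA", b = "ATGCCCAAA"))
  expect_equal(nchar(clean_codon_columns(aln2)[[1]]), 6L)
})
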