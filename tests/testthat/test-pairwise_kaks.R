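test_that("site counts match single-mutant enumeration on key codons", {
  expect_equal(ng86_site_counts("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86_site_counts("ATG"), c(s = 0, n = 3))
  expect_equal(ng86_site_counts("GGG"), oracle_sites("GGG"))
  expect_error(ng86_site_counts("TAA"), "stop")
  expect_error(ng86_site_counts("NTT"), "codon")
  # excluding stop neighbours shrinks the site total below 3
  tgg <- ng86_site_counts("TGG", stop_mutations = "exclude")
  expect_lt(sum(tgg), 3)
  expect_equal(sum(ng86_site_counts("TGG")), 3)
})

test_that("difference counts average over stop-free pathways", {
  expect_equal(ng86_diff_counts("AAA", "AAA"), c(sd = 0, nd = 0))
  expect_equal(ng86_diff_counts("TTT", "TTC"), c(sd = 1, nd = 0))
  expect_equal(ng86_diff_counts("TTT", "GTA"), oracle_diffs("TTT", "GTA"))
  # symmetric in argument order
  set.seed(50)
  cods <- sample(sense_codons(), 12)
  for (i in seq(1, 11, by = 2)) {
    expect_equal(ng86_diff_counts(cods[i], cods[i + 1]),
                 ng86_diff_counts(cods[i + 1], cods[i]))
  }
  # TGG <-> TAC keeps one stop-free pathway (via TGC) in the standard code
  expect_equal(ng86_diff_counts("TGG", "TAC"), oracle_diffs("TGG", "TAC"))
  # no standard-code pair is fully stop-blocked, so exercise the
  # all-nonsynonymous fallback with TGC additionally marked as a stop
  code2 <- genetic_code()
  code2["TGC"] <- "*"
  expect_warning(d <- ng86_diff_counts("TGG", "TAC", code = code2), "stop")
  expect_equal(d, c(sd = 0, nd = 2))
})

test_that("difference totals conserve the pathway-averaged Hamming distance", {
  set.seed(51)
  for (i in 1:20) {
    a <- sample(sense_codons(), 1)
    b <- sample(sense_codons(), 1)
    d <- suppressWarnings(ng86_diff_counts(a, b))
    hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(d["sd"] + d["nd"]), hamming)
  }
})

test_that("NG86 pair estimates match hand-enumerated examples", {
  ident <- codon_alignment(c(a = strrep("ATGAAA", 50),
                             b = strrep("ATGAAA", 50)))
  est <- kaks_ng86(ident)
  expect_equal(est$A_subs, 0)
  expect_equal(est$S_subs, 0)
  expect_equal(est$Ka, 0)
  expect_equal(est$Ks, 0)
  expect_false(est$valid)
  expect_true(is.na(est$omega))

  # TTT>TTC (syn) and GGG>GGA (syn): two synonymous one-step differences
  est2 <- kaks_ng86(codon_alignment(c(a = "TTTGGG", b = "TTCGGA")))
  expect_equal(est2$S_subs, 2)
  expect_equal(est2$A_subs, 0)
  expect_equal(est2$Ka, 0)
  s_sites <- (oracle_sites("TTT")["s"] + oracle_sites("GGG")["s"] +
                oracle_sites("TTC")["s"] + oracle_sites("GGA")["s"]) / 2
  expect_equal(est2$S_sites, unname(s_sites))
  # pS = 2 / S_sites saturates the Jukes-Cantor correction here
  expect_gte(est2$pS, 0.75)
  expect_true(is.na(est2$Ks))
  expect_false(est2$valid)
})

test_that("NG86 estimates are invariant to row order", {
  sim <- simulate_alignment(sim_config(two_tip_tree(0.3), n_genes = 1,
                                       codons_per_gene = 300, seed = 52))
  aln <- sim$alignments$gene1
  e1 <- kaks_ng86(aln)
  e2 <- kaks_ng86(codon_alignment(unclass(aln)[c(2, 1)]))
  expect_equal(e1[c("Ka", "Ks", "omega", "S_sites", "N_sites")],
               e2[c("Ka", "Ks", "omega", "S_sites", "N_sites")])
})

test_that("NG86 is unbiased for omega=1 under equal mutation rates", {
  # kappa = 1 matches the NG86 equal-rates site model; stop-adjacent
  # mutations are excluded to mirror a generator that forbids stops
  est <- sapply(1:4, function(i) {
    cfg <- sim_config(two_tip_tree(0.2), kappa = 1,
                      site_classes = data.frame(prop = 1, omega = 1),
                      n_genes = 1, codons_per_gene = 10000, seed = 520 + i)
    kaks_ng86(simulate_alignment(cfg)$alignments$gene1,
              stop_mutations = "exclude")$omega
  })
  expect_lt(abs(mean(est) - 1), 0.03)
})

test_that("two-sequence ML likelihood equals the direct codon-pair sum", {
  set.seed(53)
  sim <- simulate_alignment(sim_config(two_tip_tree(0.3), n_genes = 1,
                                       codons_per_gene = 50, seed = 53))
  aln <- sim$alignments$gene1
  kappa <- 2.5; omega <- 0.4; t <- 0.27
  pi <- rep(1 / 61, 61)
  Q <- codon_rate_matrix(kappa, omega, pi)
  P <- as.matrix(Matrix::expm(Q * t))
  cods <- sense_codons()
  i1 <- match(split_codons(aln[["A"]]), cods)
  i2 <- match(split_codons(aln[["B"]]), cods)
  direct <- sum(log(pi[i1] * P[cbind(i1, i2)]))
  via_tree <- tree_loglik(aln, two_tip_tree(t), kappa, omega, pi)
  expect_equal(via_tree, direct, tolerance = 1e-9)
})

test_that("ML on identical sequences collapses to zero divergence", {
  aln <- codon_alignment(c(a = strrep("ATGAAACCC", 30),
                           b = strrep("ATGAAACCC", 30)))
  est <- kaks_ml(aln, freq_mode = "uniform")
  expect_equal(est$t, 0)
  expect_equal(est$Ka, 0)
  expect_equal(est$Ks, 0)
})

test_that("ML and NG86 Ks agree on low-divergence simulations", {
  rel_err <- sapply(1:3, function(i) {
    cfg <- sim_config(two_tip_tree(0.1), kappa = 2,
                      site_classes = data.frame(prop = 1, omega = 0.3),
                      n_genes = 1, codons_per_gene = 3000, seed = 530 + i)
    aln <- simulate_alignment(cfg)$alignments$gene1
    ng <- kaks_ng86(aln)$Ks
    ml <- kaks_ml(aln, freq_mode = "uniform")$Ks
    abs(ml - ng) / ng
  })
  expect_lt(max(rel_err), 0.15)
})
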