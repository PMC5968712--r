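test_that("rate matrix has GY94 structure", {
  pi <- as.numeric(f3x4_freqs(matrix(c(0.3, 0.2, 0.3, 0.2,
                                       0.25, 0.25, 0.25, 0.25,
                                       0.2, 0.3, 0.2, 0.3),
                                     3, 4, byrow = TRUE)))
  Q <- codon_rate_matrix(2, 0.5, pi)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance pi_i q_ij = pi_j q_ji
  flux <- pi * Q
  expect_equal(max(abs(flux - t(flux))), 0, tolerance = 1e-15)
  # omega = 0 removes all nonsynonymous flux
  Q0 <- codon_rate_matrix(2, 0, pi, normalize = FALSE)
  code <- genetic_code()
  aa <- code[sense_codons()]
  nonsyn <- outer(aa, aa, "!=")
  expect_equal(max(abs(Q0[nonsyn & upper.tri(Q0)])), 0)
  expect_equal(max(abs(Q0[nonsyn & lower.tri(Q0)])), 0)
})

test_that("transition probabilities behave like a matrix exponential", {
  Q <- codon_rate_matrix(2, 0.5)
  pf <- congenerEvol:::pmat_factory(Q, rep(1 / 61, 61))
  expect_equal(pf(0), diag(61), tolerance = 1e-10, ignore_attr = TRUE)
  for (t in c(0.01, 0.1, 1)) {
    P <- pf(t)
    expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-9)
    expect_true(all(P >= 0))
    expect_equal(P, as.matrix(Matrix::expm(Q * t)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("F3x4 frequencies renormalize over sense codons", {
  pi <- f3x4_freqs(c("ATGAAA", "ATGCCC"))
  expect_equal(sum(pi), 1)
  expect_length(pi, 61)
  # a uniform positional matrix reweights only by stop removal
  piu <- f3x4_freqs(matrix(0.25, 3, 4))
  expect_equal(unname(piu), rep(1 / 61, 61))
})

test_that("pruning equals brute-force ancestral summation on small trees", {
  set.seed(80)
  trees <- list(
    ape::read.tree(text = "(A:0.08,B:0.15,C:0.2);"),
    ape::read.tree(text = "((A:0.1,B:0.2):0.07,C:0.15,D:0.25);")
  )
  for (tr in trees) {
    sim <- simulate_alignment(sim_config(tr, n_genes = 1,
                                         codons_per_gene = 3, seed = 81))
    aln <- sim$alignments$gene1
    for (i in 1:3) {
      kappa <- runif(1, 1, 4)
      omega <- runif(1, 0.05, 2)
      expect_equal(tree_loglik(aln, tr, kappa, omega),
                   oracle_tree_loglik(aln, tr, kappa, omega),
                   tolerance = 1e-8)
    }
  }
})

test_that("site duplication doubles the log-likelihood", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  sim <- simulate_alignment(sim_config(tr, n_genes = 1,
                                       codons_per_gene = 20, seed = 82))
  aln <- sim$alignments$gene1
  doubled <- codon_alignment(vapply(unclass(aln), function(x)
    paste0(x, x), character(1)))
  expect_equal(tree_loglik(doubled, tr, 2, 0.3),
               2 * tree_loglik(aln, tr, 2, 0.3), tolerance = 1e-9)
})

test_that("a zero-length branch never changes the likelihood", {
  tr3 <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.2);")
  tr4 <- ape::read.tree(text = "((A:0.1,B:0.1):0,C:0.2,D:0);")
  sim <- simulate_alignment(sim_config(tr3, n_genes = 1,
                                       codons_per_gene = 40, seed = 83))
  aln3 <- unclass(sim$alignments$gene1)
  # the grafted tip carries missing data, so only the zero-length branch
  # itself could perturb the likelihood
  aln4_na <- codon_alignment(c(aln3,
                               D = strrep("NNN", nchar(aln3[["A"]]) / 3)))
  expect_equal(tree_loglik(aln4_na, tr4, 2, 0.4),
               tree_loglik(codon_alignment(aln3), tr3, 2, 0.4),
               tolerance = 1e-9)
})

test_that("free-ratio fit recovers branch-specific omegas", {
  tr <- ape::read.tree(text = "(A:0.15,B:0.15,C:0.15);")
  reps <- 6L
  est <- matrix(NA_real_, reps, 3L, dimnames = list(NULL, c("A", "B", "C")))
  for (i in seq_len(reps)) {
    cfg <- sim_config(tr, kappa = 2,
                      site_classes = data.frame(prop = 1, omega = 0.5),
                      branch_omega = c(A = 0.1, B = 0.5, C = 1.5),
                      n_genes = 1, codons_per_gene = 2000, seed = 840 + i)
    sim <- simulate_alignment(cfg)
    fit <- fit_free_ratio(sim$alignments$gene1, tr)
    est[i, ] <- setNames(fit$branches$omega,
                         fit$branches$branch)[c("A", "B", "C")]
    # definitional identity Ka/Ks = omega on every branch
    with(fit$branches, expect_equal(Ka / Ks, omega, tolerance = 1e-8))
  }
  truth <- c(A = 0.1, B = 0.5, C = 1.5)
  rel_err <- abs(colMeans(est) - truth) / truth
  expect_true(all(rel_err < 0.3))
})

test_that("lineage medians summarize valid per-gene branch rates", {
  expect_equal(lineage_median(
    data.frame(branch = "A", t = 0.1, omega = 0.1, Ka = 0.01, Ks = 0.1),
    "A")[["omega"]], 0.1)
  tab <- data.frame(branch = rep("A", 4),
                    t = 0.1, omega = c(0.05, 0.10, 0.20, NA),
                    Ka = c(1, 2, 3, 4) / 100, Ks = c(0.1, 0.1, 0.1, 0))
  med <- lineage_median(tab, "A")
  expect_equal(med[["omega"]], 0.10)
  expect_equal(med[["n"]], 3)
  expect_error(lineage_median(tab, "missing"), "no valid")
})

test_that("branch-site statistic is invariant to background relabeling", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.2,D:0.3);")
  cfg <- sim_config(tr, n_genes = 1, codons_per_gene = 150, seed = 85,
                    site_classes = data.frame(prop = c(0.8, 0.2),
                                              omega = c(0.2, 1)))
  aln <- unclass(simulate_alignment(cfg)$alignments$gene1)
  fit1 <- fit_branch_site(codon_alignment(aln), tr, foreground = "A")
  # swap the labels of background tips C and D together with their
  # branch lengths: the likelihood surface is unchanged
  tr2 <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,D:0.2,C:0.3);")
  fit2 <- fit_branch_site(codon_alignment(
    setNames(aln, c("A", "B", "C", "D"))[c("A", "B", "C", "D")]
  ), tr2, foreground = "A")
  # same data, same tree shape, C/D swapped consistently
  aln3 <- aln
  names(aln3)[names(aln3) == "C"] <- "tmp"
  names(aln3)[names(aln3) == "D"] <- "C"
  names(aln3)[names(aln3) == "tmp"] <- "D"
  fit3 <- fit_branch_site(codon_alignment(aln3), tr2, foreground = "A")
  expect_equal(fit3$statistic, fit1$statistic, tolerance = 1e-4)
  expect_equal(fit3$lnL_alt, fit1$lnL_alt, tolerance = 1e-5)
})

test_that("psg scan applies the codon floor and cutoff rules", {
  tr <- congener_tree()
  cfg <- sim_config(tr, n_genes = 3, codons_per_gene = 60, seed = 86,
                    site_classes = data.frame(prop = 1, omega = 0.3))
  sim <- simulate_alignment(cfg)
  short_cfg <- sim_config(tr, n_genes = 1, codons_per_gene = 20, seed = 87,
                          site_classes = data.frame(prop = 1, omega = 0.3))
  short <- simulate_alignment(short_cfg)$alignments$gene1
  alns <- c(sim$alignments, list(tiny = short))
  res <- psg_scan(alns, tr, foreground = "Mmicrantha", fdr_cutoff = 0)
  expect_true("tiny" %in% attr(res, "excluded"))
  expect_equal(nrow(res), 3L)
  expect_false(any(res$psg))   # cutoff 0 flags nothing
  expect_true(all(res$lnL_alt >= res$lnL_null - 1e-6))
  expect_true(all(res$statistic >= 0))
})
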