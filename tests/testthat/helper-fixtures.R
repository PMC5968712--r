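# shared fixtures and small independent oracles used across test files

# random stop-free CDS of n codons
random_cds <- function(n, code = genetic_code()) {
  paste(sample(sense_codons(code), n, replace = TRUE), collapse = "")
}

two_tip_tree <- function(t = 0.1) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", t / 2, t / 2))
}

# exhaustive-path oracle for NG86 difference counting, written as a
# depth-first walk (independent of the permutation-based implementation)
oracle_diffs <- function(a, b, code = genetic_code()) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  acc <- list(sd = numeric(0), nd = numeric(0))
  walk <- function(cur, sd, nd) {
    pos <- which(cur != bv)
    if (length(pos) == 0L) {
      acc$sd <<- c(acc$sd, sd)
      acc$nd <<- c(acc$nd, nd)
      return(invisible())
    }
    for (p in pos) {
      nxt <- cur
      nxt[p] <- bv[p]
      aa1 <- code[paste(cur, collapse = "")]
      aa2 <- code[paste(nxt, collapse = "")]
      if (aa2 == "*") next
      walk(nxt, sd + (aa1 == aa2), nd + (aa1 != aa2))
    }
  }
  walk(av, 0, 0)
  if (length(acc$sd) == 0L) {
    return(c(sd = 0, nd = length(which(av != bv))))
  }
  c(sd = mean(acc$sd), nd = mean(acc$nd))
}

# single-mutant enumeration oracle for NG86 site counting
oracle_sites <- function(codon, code = genetic_code()) {
  nucs <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1L]]
  syn <- 0
  for (pos in 1:3) {
    for (nt in nucs[nucs != ch[pos]]) {
      mut <- ch
      mut[pos] <- nt
      mut_aa <- code[paste(mut, collapse = "")]
      if (mut_aa != "*" && mut_aa == code[codon]) syn <- syn + 1
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# brute-force global affine-gap alignment score by enumerating all
# alignments (exponential; only for very short sequences)
oracle_align_score <- function(a, b, mat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  best <- -Inf
  gap_cost <- function(len) if (len == 0L) 0 else gap_open + gap_extend * len
  rec <- function(i, j, score, state) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1L, j + 1L, score + mat[av[i], bv[j]], "m")
    }
    if (i <= length(av)) {
      pen <- if (state == "ga") gap_extend else gap_cost(1L)
      rec(i + 1L, j, score - pen, "ga")
    }
    if (j <= length(bv)) {
      pen <- if (state == "gb") gap_extend else gap_cost(1L)
      rec(i, j + 1L, score - pen, "gb")
    }
  }
  rec(1L, 1L, 0, "m")
  best
}

# brute-force tree likelihood: sum over all internal-node state
# combinations (only for tiny trees / few sites)
oracle_tree_loglik <- function(aln, tree, kappa, omega, pi = NULL,
                               code = genetic_code()) {
  cods <- sense_codons(code)
  if (is.null(pi)) pi <- rep(1 / length(cods), length(cods))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1L):nnode
  Q <- codon_rate_matrix(kappa, omega, pi, code)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  tipstate <- sapply(tree$tip.label, function(tl)
    match(split_codons(aln[[tl]]), cods))
  if (is.vector(tipstate)) tipstate <- matrix(tipstate, nrow = 1L)
  nsites <- nrow(tipstate)
  ll <- 0
  n <- length(cods)
  for (s in seq_len(nsites)) {
    combos <- as.matrix(expand.grid(rep(list(seq_len(n)),
                                        length(internal))))
    tot <- 0
    for (r in seq_len(nrow(combos))) {
      states <- integer(nnode)
      states[seq_len(ntip)] <- tipstate[s, ]
      states[internal] <- combos[r, ]
      pr <- pi[states[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * P[[e]][states[tree$edge[e, 1L]], states[tree$edge[e, 2L]]]
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}
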