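#' Configuration for codon-alignment simulation
#'
#' Describes the generative GY94-type process: root codons are drawn from
#' the stationary frequencies and evolved along each branch by exact
#' stochastic jumps (Gillespie), per codon, under the branch- and
#' site-specific omega. The generator is scaled so that one branch-length
#' unit equals one expected substitution per codon under the gene-average
#' (background) model; branch or foreground omega overrides therefore
#' change realized substitution counts, not the clock.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param kappa transition/transversion ratio (default 2).
#' @param codon_freqs `"uniform"`, a 61-vector over [sense_codons()], or a
#'   3x4 positional nucleotide frequency matrix (F3x4).
#' @param site_classes data.frame with columns `prop` (summing to 1) and
#'   `omega`, plus optionally `omega_fg` giving each class's omega on the
#'   foreground branch (branch-site style heterogeneity).
#' @param branch_omega optional named vector over branch labels (tip
#'   labels / `"node<N>"`) overriding omega for all site classes on those
#'   branches (free-ratio style heterogeneity).
#' @param foreground tip label of the foreground branch (needed when
#'   `omega_fg` is used); defaults to the `#1`-marked tip, if any.
#' @param n_genes number of independent genes to simulate.
#' @param codons_per_gene gene length in codons.
#' @param seed integer seed; identical configurations give identical
#'   output, and per-gene streams are pre-split so gene order is
#'   irrelevant.
#' @param code genetic code.
#' @return Validated configuration list of class `sim_config`.
#' @export
sim_config <- function(tree, kappa = 2, codon_freqs = "uniform",
                       site_classes = data.frame(prop = 1, omega = 0.2),
                       branch_omega = NULL, foreground = NULL,
                       n_genes = 1L, codons_per_gene = 300L, seed = 1L,
                       code = genetic_code()) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  if (n_genes < 1L) stop("n_genes must be at least 1")
  if (codons_per_gene < 1L) stop("zero-length genes cannot be simulated")
  if (abs(sum(site_classes$prop) - 1) > 1e-12) {
    stop("site-class proportions must sum to 1")
  }
  if (any(site_classes$prop < 0) || any(site_classes$omega < 0)) {
    stop("site-class proportions and omegas must be non-negative")
  }
  if (!is.null(site_classes$omega_fg) && any(site_classes$omega_fg < 0)) {
    stop("foreground omegas must be non-negative")
  }
  if (is.null(foreground)) {
    fg <- foreground_tip(tree)
    if (!is.na(fg)) foreground <- fg
  }
  if (!is.null(site_classes$omega_fg) && is.null(foreground)) {
    stop("omega_fg site classes require a foreground branch")
  }
  pi <- if (identical(codon_freqs, "uniform")) {
    codon_frequencies("uniform", code = code)
  } else if (is.matrix(codon_freqs)) {
    f3x4_freqs(codon_freqs, code)
  } else {
    check_codon_freqs(codon_freqs, length(sense_codons(code)))
  }
  structure(
    list(tree = tree, kappa = kappa, pi = pi, site_classes = site_classes,
         branch_omega = branch_omega, foreground = foreground,
         n_genes = as.integer(n_genes),
         codons_per_gene = as.integer(codons_per_gene),
         seed = as.integer(seed), code = code),
    class = "sim_config"
  )
}

# jump machinery for one omega: exit rates and per-state jump CDFs of the
# (unnormalized-then-scaled) GY94 generator
jump_tables <- function(kappa, omega, pi, scale, code) {
  Q <- codon_rate_matrix(kappa, omega, pi, code, normalize = FALSE) / scale
  rate_out <- -diag(Q)
  Jp <- Q
  diag(Jp) <- 0
  Jp <- Jp / rate_out
  cdf <- t(apply(Jp, 1L, cumsum))
  list(rate_out = rate_out, cdf = cdf)
}

# evolve integer codon states for time t under one jump table; returns new
# states and realized synonymous / nonsynonymous event counts
evolve_states <- function(states, t, jt, syn_pair) {
  n_syn <- 0L
  n_nonsyn <- 0L
  if (t <= 0 || length(states) == 0L) {
    return(list(states = states, n_syn = 0L, n_nonsyn = 0L))
  }
  rem <- rep(t, length(states))
  active <- seq_along(states)
  while (length(active) > 0L) {
    w <- stats::rexp(length(active), jt$rate_out[states[active]])
    hit <- w < rem[active]
    rem[active] <- rem[active] - w
    active <- active[hit]
    if (length(active) == 0L) break
    u <- stats::runif(length(active))
    s <- states[active]
    nxt <- rowSums(jt$cdf[s, , drop = FALSE] < u) + 1L
    syn <- syn_pair[cbind(s, nxt)]
    n_syn <- n_syn + sum(syn)
    n_nonsyn <- n_nonsyn + sum(!syn)
    states[active] <- nxt
  }
  list(states = states, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

# simulate one gene; assumes the RNG state is already set
simulate_gene <- function(config) {
  edges <- tree_edges(config$tree)
  cls <- config$site_classes
  n_class <- nrow(cls)
  nc <- config$codons_per_gene
  code <- config$code
  cods <- sense_codons(code)
  aa <- code[cods]
  syn_pair <- outer(aa, aa, "==")
  # gene-average clock: expected substitutions per codon per unit time = 1
  # under the background class mixture
  class_rate <- vapply(cls$omega, function(w) {
    Q <- codon_rate_matrix(config$kappa, w, config$pi, code,
                           normalize = FALSE)
    -sum(config$pi * diag(Q))
  }, numeric(1L))
  scale <- sum(cls$prop * class_rate)
  fg_edge <- if (!is.null(config$foreground)) {
    foreground_edge(edges, config$foreground)
  } else NA_integer_
  # omega per (class, edge)
  omega_mat <- matrix(rep(cls$omega, nrow(edges$edge)), nrow = n_class)
  if (!is.null(cls$omega_fg) && !is.na(fg_edge)) {
    omega_mat[, fg_edge] <- cls$omega_fg
  }
  if (!is.null(config$branch_omega)) {
    for (b in names(config$branch_omega)) {
      e <- which(edges$label == b)
      if (length(e) != 1L) stop("branch_omega names unknown branch '", b, "'")
      omega_mat[, e] <- config$branch_omega[[b]]
    }
  }
  jts <- list()
  jt_for <- function(w) {
    key <- format(w, digits = 17)
    if (is.null(jts[[key]])) {
      jts[[key]] <<- jump_tables(config$kappa, w, config$pi, scale, code)
    }
    jts[[key]]
  }
  site_class <- sample.int(n_class, nc, replace = TRUE, prob = cls$prop)
  nnode <- edges$ntip + edges$tree$Nnode
  node_states <- vector("list", nnode)
  node_states[[edges$root]] <- sample.int(length(cods), nc, replace = TRUE,
                                          prob = config$pi)
  counts <- data.frame(branch = edges$label,
                       n_syn = 0L, n_nonsyn = 0L,
                       stringsAsFactors = FALSE)
  for (e in rev(seq_len(nrow(edges$edge)))) {   # preorder
    parent <- edges$edge[e, 1L]
    child <- edges$edge[e, 2L]
    states <- node_states[[parent]]
    for (cl in seq_len(n_class)) {
      idx <- which(site_class == cl)
      if (length(idx) == 0L) next
      ev <- evolve_states(states[idx], edges$length[e],
                          jt_for(omega_mat[cl, e]), syn_pair)
      states[idx] <- ev$states
      counts$n_syn[e] <- counts$n_syn[e] + ev$n_syn
      counts$n_nonsyn[e] <- counts$n_nonsyn[e] + ev$n_nonsyn
    }
    node_states[[child]] <- states
  }
  tip_rows <- vapply(seq_len(edges$ntip), function(i) {
    paste(cods[node_states[[i]]], collapse = "")
  }, character(1L))
  names(tip_rows) <- strip_foreground_labels(edges$tree$tip.label)
  list(alignment = codon_alignment(tip_rows),
       site_class = site_class,
       branch_counts = counts,
       omega = omega_mat)
}

#' Simulate codon alignments on a tree
#'
#' @param config [sim_config()] object.
#' @return List with `alignments` (named list of [codon_alignment()]s,
#'   `gene1`, `gene2`, ...) and `truth`: per-gene site-class assignments,
#'   realized per-branch synonymous/nonsynonymous substitution counts, and
#'   the per-(class, branch) omega actually used.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, config$n_genes)
  alignments <- vector("list", config$n_genes)
  truth <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    set.seed(gene_seeds[g])
    sim <- simulate_gene(config)
    alignments[[g]] <- sim$alignment
    truth[[g]] <- sim[c("site_class", "branch_counts", "omega")]
  }
  names(alignments) <- names(truth) <- paste0("gene", seq_len(config$n_genes))
  list(alignments = alignments, truth = truth)
}

#' Simulate a gene family set with planted accelerated categories
#'
#' Genes are assigned round-robin to `n_categories` functional categories;
#' genes falling in `accelerated` categories evolve on the foreground
#' branch with every site-class omega multiplied by `multiplier`.
#'
#' @param config [sim_config()] with a foreground branch set.
#' @param n_categories number of categories.
#' @param accelerated character vector of accelerated category ids (subset
#'   of `sprintf("CAT%03d", 1:n_categories)`), or an integer vector of
#'   category indices.
#' @param multiplier foreground omega multiplier (>= 0) for accelerated
#'   categories; 1 plants nothing.
#' @return List with `alignments`, `annotation` (data.frame `gene`,
#'   `category`), and `truth` (accelerated category ids, multiplier, plus
#'   the per-gene truth of [simulate_alignment()]).
#' @export
simulate_family_set <- function(config, n_categories,
                                accelerated = character(0), multiplier = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (multiplier < 0) stop("multiplier must be non-negative")
  if (is.null(config$foreground)) stop("config must set a foreground branch")
  cat_ids <- sprintf("CAT%03d", seq_len(n_categories))
  if (is.numeric(accelerated)) accelerated <- cat_ids[accelerated]
  if (!all(accelerated %in% cat_ids)) stop("unknown accelerated category id")
  if (multiplier == 1) accelerated_out <- character(0) else
    accelerated_out <- accelerated
  gene_ids <- paste0("gene", seq_len(config$n_genes))
  gene_cat <- cat_ids[(seq_len(config$n_genes) - 1L) %% n_categories + 1L]
  set.seed(config$seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, config$n_genes)
  cls <- config$site_classes
  accel_config <- config
  accel_config$site_classes$omega_fg <-
    (if (is.null(cls$omega_fg)) cls$omega else cls$omega_fg) * multiplier
  alignments <- vector("list", config$n_genes)
  truth_genes <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    set.seed(gene_seeds[g])
    cfg <- if (gene_cat[g] %in% accelerated) accel_config else config
    sim <- simulate_gene(cfg)
    alignments[[g]] <- sim$alignment
    truth_genes[[g]] <- sim[c("site_class", "branch_counts", "omega")]
  }
  names(alignments) <- names(truth_genes) <- gene_ids
  list(
    alignments = alignments,
    annotation = data.frame(gene = gene_ids, category = gene_cat,
                            stringsAsFactors = FALSE),
    truth = list(accelerated = accelerated_out, multiplier = multiplier,
                 genes = truth_genes)
  )
}

#' Configuration for negative-binomial count simulation
#'
#' @param n_genes number of genes.
#' @param mean_log2_cpm,sd_log2_cpm log2-normal distribution of baseline
#'   expression (CPM scale) across genes.
#' @param dispersion NB dispersion phi >= 0 (phi = 0 gives Poisson
#'   counts).
#' @param lib_sizes named vector of per-sample library sizes (> 0).
#' @param de_fraction fraction of genes planted as differentially
#'   expressed (default 0).
#' @param log2_fc absolute log2 fold change of planted genes; each planted
#'   gene is up- or down-shifted (random sign) in `de_sample`.
#' @param de_sample index of the sample carrying the shift (default 2).
#' @param seed integer seed.
#' @return Configuration list of class `nb_count_config`.
#' @export
nb_count_config <- function(n_genes, mean_log2_cpm = 5, sd_log2_cpm = 2,
                            dispersion = 0.2,
                            lib_sizes = c(s1 = 2e7, s2 = 2e7),
                            de_fraction = 0, log2_fc = 2, de_sample = 2L,
                            seed = 1L) {
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  if (is.null(names(lib_sizes))) {
    names(lib_sizes) <- paste0("s", seq_along(lib_sizes))
  }
  structure(
    list(n_genes = as.integer(n_genes), mean_log2_cpm = mean_log2_cpm,
         sd_log2_cpm = sd_log2_cpm, dispersion = dispersion,
         lib_sizes = lib_sizes, de_fraction = de_fraction,
         log2_fc = log2_fc, de_sample = as.integer(de_sample),
         seed = as.integer(seed)),
    class = "nb_count_config"
  )
}

#' Simulate a count matrix with planted differentially expressed genes
#'
#' @param config [nb_count_config()] object.
#' @return List with `counts` (integer genes-by-samples matrix carrying a
#'   `lib.sizes` attribute) and `truth` (data.frame of planted genes with
#'   their signed log2 fold changes; empty when `de_fraction` is 0 or
#'   `log2_fc` is 0).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "nb_count_config"))
  set.seed(config$seed)
  n <- config$n_genes
  samples <- names(config$lib_sizes)
  lambda <- 2^stats::rnorm(n, config$mean_log2_cpm, config$sd_log2_cpm)
  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0L) sample.int(n, n_de) else integer(0)
  sign_up <- stats::runif(length(de_idx)) < 0.5
  lfc <- numeric(n)
  lfc[de_idx] <- ifelse(sign_up, config$log2_fc, -config$log2_fc)
  counts <- matrix(0L, n, length(samples),
                   dimnames = list(paste0("g", seq_len(n)), samples))
  for (s in seq_along(samples)) {
    mu <- lambda * config$lib_sizes[[s]] / 1e6
    if (s == config$de_sample) mu <- mu * 2^lfc
    counts[, s] <- if (config$dispersion == 0) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = 1 / config$dispersion, mu = mu)
    }
  }
  attr(counts, "lib.sizes") <- stats::setNames(config$lib_sizes, samples)
  de <- de_idx[lfc[de_idx] != 0]
  list(counts = counts,
       truth = data.frame(gene = rownames(counts)[de],
                          log2_fc = lfc[de], stringsAsFactors = FALSE))
}
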