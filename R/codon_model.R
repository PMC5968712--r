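#' GY94-type codon substitution models
#'
#' The substitution process over the 61 sense codons follows the
#' Goldman-Yang parameterization: the instantaneous rate from codon i to
#' codon j is nonzero only for single-nucleotide changes and proportional to
#' the target frequency pi_j, multiplied by kappa for transitions and by
#' omega for nonsynonymous changes. The generator is scaled so one time unit
#' equals one expected substitution per codon, the branch-length convention
#' of codeml-style software.
#'
#' @name codon_model
NULL

.model_cache <- new.env(parent = emptyenv())

# Structural description of single-step sense-codon changes for a code:
# index pairs plus transition / nonsynonymous flags.
codon_model_structure <- function(code = genetic_code()) {
  key <- paste(code, collapse = "")
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  cods <- sense_codons(code)
  n <- length(cods)
  chars <- do.call(rbind, strsplit(cods, ""))
  ii <- integer(0); jj <- integer(0); ts <- logical(0); nonsyn <- logical(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diffpos <- which(chars[i, ] != chars[j, ])
      if (length(diffpos) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, is_transition(chars[i, diffpos], chars[j, diffpos]))
      nonsyn <- c(nonsyn, code[cods[i]] != code[cods[j]])
    }
  }
  out <- list(codons = cods, n = n, ii = ii, jj = jj, ts = ts, nonsyn = nonsyn)
  .model_cache[[key]] <- out
  out
}

#' GY94 rate matrix
#'
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi codon frequencies: numeric 61-vector summing to 1 (order of
#'   [sense_codons()]), or `NULL` for uniform.
#' @param code genetic code.
#' @param normalize scale to one expected substitution per codon per unit
#'   time (default `TRUE`).
#' @return 61x61 generator matrix with zero row sums.
#' @export
codon_rate_matrix <- function(kappa, omega, pi = NULL, code = genetic_code(),
                              normalize = TRUE) {
  st <- codon_model_structure(code)
  pi <- check_codon_freqs(pi, st$n)
  Q <- matrix(0, st$n, st$n, dimnames = list(st$codons, st$codons))
  rate <- pi[st$jj] * ifelse(st$ts, kappa, 1) * ifelse(st$nonsyn, omega, 1)
  Q[cbind(st$ii, st$jj)] <- rate
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

check_codon_freqs <- function(pi, n = 61L) {
  if (is.null(pi)) return(rep(1 / n, n))
  if (length(pi) != n) stop("codon frequency vector must have length ", n)
  if (any(pi < 0)) stop("codon frequencies must be non-negative")
  s <- sum(pi)
  if (abs(s - 1) > 1e-6) stop("codon frequencies must sum to 1")
  pi / s
}

# Symmetric spectral decomposition of a reversible generator; returns a
# closure computing P(t) = exp(Qt).
pmat_factory <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- (Q * rep(sq, each = nrow(Q))) / rep(sq, times = ncol(Q))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- eig$vectors
  lam <- eig$values
  A <- U / sq          # D^{-1/2} U
  Bt <- t(U * sq)      # U' D^{1/2}
  function(t) {
    P <- A %*% (exp(lam * t) * Bt)
    P[P < 0] <- 0
    P
  }
}

#' F3x4 codon frequencies
#'
#' Codon frequencies proportional to the product of position-specific
#' nucleotide frequencies, with stop codons zeroed and the remainder
#' renormalized.
#'
#' @param x either a 3x4 matrix of positional nucleotide frequencies
#'   (rows = codon positions, columns = A, C, G, T) or a character vector
#'   of (gapped) coding sequences from which the positional frequencies are
#'   tabulated.
#' @param code genetic code.
#' @return Numeric 61-vector over [sense_codons()].
#' @export
f3x4_freqs <- function(x, code = genetic_code()) {
  if (is.character(x)) {
    f <- matrix(0, 3, 4, dimnames = list(NULL, NUCS))
    for (seqs in x) {
      cod <- split_codons(ungap(seqs))
      ch <- strsplit(cod, "")
      ch <- do.call(rbind, ch)
      if (is.null(ch)) next
      for (p in 1:3) {
        tab <- table(factor(ch[, p], levels = NUCS))
        f[p, ] <- f[p, ] + as.numeric(tab)
      }
    }
    if (any(rowSums(f) == 0)) stop("no countable nucleotides in input")
    f <- f / rowSums(f)
  } else {
    f <- x
    if (!is.matrix(f) || any(dim(f) != c(3, 4))) {
      stop("positional frequencies must be a 3x4 matrix")
    }
    colnames(f) <- NUCS
    f <- f / rowSums(f)
  }
  cods <- sense_codons(code)
  ch <- do.call(rbind, strsplit(cods, ""))
  pi <- f[cbind(1L, match(ch[, 1], NUCS))] *
    f[cbind(2L, match(ch[, 2], NUCS))] *
    f[cbind(3L, match(ch[, 3], NUCS))]
  pi <- pi / sum(pi)
  stats::setNames(pi, cods)
}

#' Codon frequency choices used by the estimators
#'
#' @param mode `"uniform"` or `"f3x4"`.
#' @param aln alignment (needed for `"f3x4"`).
#' @param code genetic code.
#' @return Numeric 61-vector.
#' @export
codon_frequencies <- function(mode = c("f3x4", "uniform"), aln = NULL,
                              code = genetic_code()) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    n <- length(sense_codons(code))
    return(stats::setNames(rep(1 / n, n), sense_codons(code)))
  }
  if (is.null(aln)) stop("an alignment is required for F3x4 frequencies")
  f3x4_freqs(as.character(aln), code)
}

# --- alignment -> integer codon states -------------------------------------

# Tip-state matrix with site-pattern compression. Codons that are not
# unambiguous sense codons become NA (missing data: likelihood 1 over all
# states).
aln_patterns <- function(aln, code = genetic_code()) {
  aln <- codon_alignment(aln)
  m <- codon_matrix(aln)
  cods <- sense_codons(code)
  states <- matrix(match(m, cods), nrow = nrow(m),
                   dimnames = list(rownames(m), NULL))
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(key)[key[first]])
  list(states = states[, first, drop = FALSE], weights = weights,
       n_sites = ncol(states))
}

# --- tree utilities --------------------------------------------------------

# Postorder edge traversal with branch labels: terminal branches are named
# after their (mark-stripped) tip, internal ones "node<N>".
tree_edges <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2L]
  label <- ifelse(child <= ntip,
                  strip_foreground_labels(tree$tip.label[child]),
                  paste0("node", child))
  list(tree = tree, edge = tree$edge, ntip = ntip,
       root = ntip + 1L, label = label,
       length = if (is.null(tree$edge.length)) rep(NA_real_, nrow(tree$edge))
                else tree$edge.length)
}

# --- pruning likelihood ----------------------------------------------------

# Felsenstein pruning over 61 codon states for a site-class mixture.
# omega_mat: n_class x n_edge; props: class proportions; t: branch lengths.
#
# Time scaling: with a single site class, each branch's generator is
# normalized by its own omega (one branch-length unit = one expected
# substitution per codon on that branch, the free-ratio convention). With
# several classes all of them must share one clock, otherwise a fast class
# cannot produce excess divergence: `scale_omegas` names the per-class
# background omegas and the common scale is the background-mixture mean
# rate, the same convention the simulator uses.
mixture_loglik <- function(patterns, edges, kappa, pi, omega_mat, props, t,
                           code = genetic_code(), scale_omegas = NULL) {
  n_class <- nrow(omega_mat)
  n_edge <- nrow(edges$edge)
  nstate <- length(pi)
  npat <- ncol(patterns$states)
  # one spectral decomposition per distinct omega (unnormalized generator)
  omegas <- sort(unique(c(as.numeric(omega_mat), scale_omegas)))
  Qs <- lapply(omegas, function(w)
    codon_rate_matrix(kappa, w, pi, code, normalize = FALSE))
  mu <- vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1L))
  fact <- lapply(Qs, pmat_factory, pi = pi)
  mix_scale <- if (is.null(scale_omegas)) NA_real_ else
    sum(props * mu[match(scale_omegas, omegas)])
  sitelik <- rep(0, npat)
  tipnames <- rownames(patterns$states)
  nnode <- edges$ntip + edges$tree$Nnode
  pcache <- vector("list", length(omegas) * n_edge)
  for (cl in seq_len(n_class)) {
    partial <- vector("list", nnode)
    for (e in seq_len(n_edge)) {
      parent <- edges$edge[e, 1L]
      child <- edges$edge[e, 2L]
      wi <- match(omega_mat[cl, e], omegas)
      ci <- (wi - 1L) * n_edge + e
      if (is.null(pcache[[ci]])) {
        s <- if (is.null(scale_omegas)) mu[wi] else mix_scale
        pcache[[ci]] <- fact[[wi]](t[e] / s)
      }
      P <- pcache[[ci]]
      if (child <= edges$ntip) {
        s <- patterns$states[match(edges$label[e], tipnames), ]
        down <- matrix(1, nstate, npat)
        ok <- !is.na(s)
        down[, ok] <- P[, s[ok]]
      } else {
        down <- P %*% partial[[child]]
      }
      partial[[parent]] <- if (is.null(partial[[parent]])) down
                           else partial[[parent]] * down
    }
    sitelik <- sitelik + props[cl] * as.numeric(pi %*% partial[[edges$root]])
  }
  sum(patterns$weights * log(sitelik))
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over the 61 sense-codon states under a GY94 model,
#' optionally as a mixture of site classes. Codons that are not unambiguous
#' sense codons are treated as missing data.
#'
#' @param aln codon alignment whose ids include every tip label of `tree`.
#' @param tree `phylo` tree with branch lengths (expected substitutions per
#'   codon).
#' @param kappa transition/transversion ratio.
#' @param pi codon frequencies (61-vector) or `NULL` for uniform.
#' @param omega either a single ratio applied to every branch, a named
#'   vector over branch labels (tip labels for terminal branches,
#'   `"node<N>"` for internal ones), or for site-class mixtures a list with
#'   elements `classes` (data.frame with columns `prop`, `omega_bg`,
#'   `omega_fg`) and `foreground` (tip label of the foreground branch).
#' @param code genetic code.
#' @return Log-likelihood (numeric scalar).
#' @export
tree_loglik <- function(aln, tree, kappa, omega, pi = NULL,
                        code = genetic_code()) {
  edges <- tree_edges(tree)
  missing_tips <- setdiff(edges$label[edges$edge[, 2L] <= edges$ntip],
                          names(aln))
  if (length(missing_tips) > 0L) {
    stop("no sequence for tip '", missing_tips[1L], "'")
  }
  if (any(is.na(edges$length))) stop("tree must have branch lengths")
  patterns <- aln_patterns(aln, code)
  pi <- check_codon_freqs(pi, length(sense_codons(code)))
  n_edge <- nrow(edges$edge)
  scale_omegas <- NULL
  if (is.list(omega)) {
    cls <- omega$classes
    fg_edge <- foreground_edge(edges, omega$foreground)
    omega_mat <- matrix(rep(cls$omega_bg, n_edge), nrow = nrow(cls))
    omega_mat[, fg_edge] <- cls$omega_fg
    props <- cls$prop
    scale_omegas <- cls$omega_bg
  } else if (length(omega) == 1L && is.null(names(omega))) {
    omega_mat <- matrix(omega, 1L, n_edge)
    props <- 1
  } else {
    if (!all(edges$label %in% names(omega))) {
      stop("per-branch omega must name every branch")
    }
    omega_mat <- matrix(omega[edges$label], 1L, n_edge)
    props <- 1
  }
  mixture_loglik(patterns, edges, kappa, pi, omega_mat, props,
                 edges$length, code, scale_omegas = scale_omegas)
}

foreground_edge <- function(edges, foreground) {
  hit <- which(edges$label == foreground & edges$edge[, 2L] <= edges$ntip)
  if (length(hit) != 1L) {
    stop("foreground tip '", foreground, "' not found in tree")
  }
  hit
}
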