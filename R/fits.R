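#' Maximum-likelihood pairwise Ka/Ks under a GY94 model
#'
#' Maximizes the two-sequence likelihood sum over sites of
#' log(sum_ij pi_i P_ij(t)) in (t, kappa, omega), then decomposes the
#' fitted divergence t into nonsynonymous and synonymous flux per site:
#' Ka = t rhoN / (3 fN) and Ks = t rhoS / (3 fS), where rho are the
#' nonsynonymous/synonymous rate fractions of the fitted generator and f
#' the corresponding site (mutational-opportunity) fractions of the same
#' generator with omega = 1. By construction Ka/Ks equals the fitted omega.
#'
#' @param aln two-row codon alignment.
#' @param freq_mode `"f3x4"` (positional frequencies estimated from the
#'   pair) or `"uniform"`.
#' @param code genetic code.
#' @return One-row `data.frame` with the same columns as [kaks_ng86()]
#'   plus `t`, `kappa`; `method` is `"ML"`. Non-convergence is reported via
#'   `valid = FALSE`.
#' @export
kaks_ml <- function(aln, freq_mode = c("f3x4", "uniform"),
                    code = genetic_code()) {
  freq_mode <- match.arg(freq_mode)
  aln <- codon_alignment(aln)
  if (length(aln) != 2L) stop("pairwise ML estimation needs exactly two sequences")
  aln <- clean_codon_columns(aln, code)
  m <- codon_matrix(aln)
  nc <- ncol(m)
  if (nc < 1L) stop("no comparable codon columns between the two sequences")
  cods <- sense_codons(code)
  pi <- codon_frequencies(freq_mode, aln, code)
  i1 <- match(m[1L, ], cods)
  i2 <- match(m[2L, ], cods)
  counts <- table(factor(i1, seq_along(cods)), factor(i2, seq_along(cods)))
  counts <- unclass(counts)
  obs <- which(counts > 0, arr.ind = TRUE)
  nobs <- counts[obs]
  pair_id <- paste(names(aln), collapse = ":")

  if (all(i1 == i2)) {
    return(ml_row(pair_id, nc, t = 0, kappa = NA_real_, omega = NA_real_,
                  pi = pi, code = code, valid = FALSE))
  }
  negll <- function(par) {
    t <- exp(par[1L]); kappa <- exp(par[2L]); omega <- exp(par[3L])
    Q <- codon_rate_matrix(kappa, omega, pi, code)
    P <- pmat_factory(Q, pi)(t)
    lik <- pi[obs[, 1L]] * P[obs]
    if (any(lik <= 0)) return(1e10)
    -sum(nobs * log(lik))
  }
  best <- NULL
  for (t0 in c(0.01, 0.1, 0.5)) {
    fit <- stats::nlminb(log(c(t0, 2, 0.5)), negll,
                         lower = log(c(1e-6, 1e-2, 1e-6)),
                         upper = log(c(50, 100, 99)),
                         control = list(rel.tol = 1e-10, iter.max = 500))
    if (is.null(best) || fit$objective < best$objective - 1e-9) best <- fit
  }
  valid <- !is.null(best) && best$convergence %in% c(0L, 1L)
  t_hat <- exp(best$par[1L]); kappa_hat <- exp(best$par[2L])
  omega_hat <- exp(best$par[3L])
  ml_row(pair_id, nc, t_hat, kappa_hat, omega_hat, pi, code, valid)
}

# assemble a KaKs result row from fitted (t, kappa, omega)
ml_row <- function(pair_id, nc, t, kappa, omega, pi, code, valid) {
  if (is.na(omega)) {
    fr <- flux_fractions(1, ifelse(is.na(kappa), 2, kappa), pi, code)
    S_sites <- 3 * fr$fS * nc
    N_sites <- 3 * fr$fN * nc
    return(data.frame(pair = pair_id, n_codons = nc,
                      S_sites = S_sites, N_sites = N_sites,
                      S_subs = 0, A_subs = 0, pS = 0, pN = 0,
                      Ks = 0, Ka = 0, omega = NA_real_,
                      method = "ML", valid = valid,
                      t = t, kappa = kappa, stringsAsFactors = FALSE))
  }
  fr <- flux_fractions(omega, kappa, pi, code)
  S_sites <- 3 * fr$fS * nc
  N_sites <- 3 * fr$fN * nc
  Ka <- t * fr$rhoN / (3 * fr$fN)
  Ks <- t * fr$rhoS / (3 * fr$fS)
  data.frame(pair = pair_id, n_codons = nc,
             S_sites = S_sites, N_sites = N_sites,
             S_subs = Ks * S_sites, A_subs = Ka * N_sites,
             pS = NA_real_, pN = NA_real_,
             Ks = Ks, Ka = Ka, omega = omega,
             method = "ML", valid = valid,
             t = t, kappa = kappa, stringsAsFactors = FALSE)
}

# Nonsynonymous/synonymous flux fractions of Q(kappa, omega, pi), and site
# fractions = flux fractions of the neutral (omega = 1) matrix.
flux_fractions <- function(omega, kappa, pi, code = genetic_code()) {
  st <- codon_model_structure(code)
  pi <- check_codon_freqs(pi, st$n)
  flux <- function(w) {
    r <- pi[st$ii] * pi[st$jj] * ifelse(st$ts, kappa, 1) *
      ifelse(st$nonsyn, w, 1)
    c(N = sum(r[st$nonsyn]), S = sum(r[!st$nonsyn]))
  }
  fw <- flux(omega)
  f1 <- flux(1)
  list(rhoN = fw[["N"]] / sum(fw), rhoS = fw[["S"]] / sum(fw),
       fN = f1[["N"]] / sum(f1), fS = f1[["S"]] / sum(f1))
}

#' Free-ratio model: an independent omega per branch
#'
#' Jointly maximizes the pruning likelihood in kappa and per-branch
#' (t, omega); per-branch Ka and Ks are then obtained by apportioning each
#' fitted branch length into nonsynonymous and synonymous flux per site
#' (see [kaks_ml()]), so Ka/Ks equals the branch omega whenever Ks > 0.
#'
#' @param aln codon alignment covering the tips of `tree`.
#' @param tree unrooted `phylo` tree with at least 3 tips; branch lengths,
#'   when present, seed the optimizer.
#' @param pi codon frequencies or `NULL` for uniform.
#' @param code genetic code.
#' @return List with `branches` (data.frame: `branch`, `t`, `omega`, `Ka`,
#'   `Ks`), `kappa`, `lnL`, `convergence`.
#' @export
fit_free_ratio <- function(aln, tree, pi = NULL, code = genetic_code()) {
  edges <- tree_edges(tree)
  if (edges$ntip < 3L) stop("free-ratio fitting needs a tree with >= 3 tips")
  patterns <- aln_patterns(aln[intersect(names(aln), edges$label)], code)
  pi <- check_codon_freqs(pi, length(sense_codons(code)))
  n_edge <- nrow(edges$edge)
  t0 <- ifelse(is.na(edges$length) | edges$length <= 0, 0.1, edges$length)
  negll <- function(par) {
    kappa <- exp(par[1L])
    t <- exp(par[1L + seq_len(n_edge)])
    w <- exp(par[1L + n_edge + seq_len(n_edge)])
    -mixture_loglik(patterns, edges, kappa, pi,
                    matrix(w, 1L, n_edge), 1, t, code)
  }
  lower <- c(log(1e-2), rep(log(1e-4), n_edge), rep(log(1e-4), n_edge))
  upper <- c(log(100), rep(log(50), n_edge), rep(log(99), n_edge))
  best <- NULL
  for (w0 in c(0.3, 1.0)) {
    fit <- stats::nlminb(log(c(2, t0, rep(w0, n_edge))), negll,
                         lower = lower, upper = upper,
                         control = list(rel.tol = 1e-10, iter.max = 500))
    if (is.null(best) || fit$objective < best$objective - 1e-9) best <- fit
  }
  kappa <- exp(best$par[1L])
  t <- exp(best$par[1L + seq_len(n_edge)])
  w <- exp(best$par[1L + n_edge + seq_len(n_edge)])
  fr <- lapply(w, flux_fractions, kappa = kappa, pi = pi, code = code)
  branches <- data.frame(
    branch = edges$label,
    t = t, omega = w,
    Ka = t * vapply(fr, function(f) f$rhoN / (3 * f$fN), numeric(1L)),
    Ks = t * vapply(fr, function(f) f$rhoS / (3 * f$fS), numeric(1L)),
    stringsAsFactors = FALSE
  )
  list(branches = branches, kappa = kappa, lnL = -best$objective,
       convergence = best$convergence %in% c(0L, 1L))
}

#' Lineage-representative rates from per-gene free-ratio fits
#'
#' The median, rather than the mean, is taken to represent a lineage
#' because it is robust to the extreme per-gene ratios that arise when Ks
#' is near zero. Genes whose branch omega is undefined or whose Ks is zero
#' are excluded.
#'
#' @param branch_fits data.frame of per-gene branch rows (as produced by
#'   stacking `fit_free_ratio()$branches` with a `gene` column), or a list
#'   of such data.frames.
#' @param lineage branch label (tip name) to summarize.
#' @return Named numeric vector with `omega`, `Ka`, `Ks` medians and `n`.
#' @export
lineage_median <- function(branch_fits, lineage) {
  if (is.list(branch_fits) && !is.data.frame(branch_fits)) {
    branch_fits <- do.call(rbind, branch_fits)
  }
  rows <- branch_fits[branch_fits$branch == lineage, , drop = FALSE]
  rows <- rows[is.finite(rows$omega) & is.finite(rows$Ks) & rows$Ks > 0, ,
               drop = FALSE]
  if (nrow(rows) == 0L) stop("no valid estimates for lineage '", lineage, "'")
  c(omega = stats::median(rows$omega), Ka = stats::median(rows$Ka),
    Ks = stats::median(rows$Ks), n = nrow(rows))
}

# --- branch-site model A ---------------------------------------------------

# proportions (p0, p1, p2a, p2b) from two free parameters on the simplex
bs_props <- function(x0, x1) {
  e0 <- exp(x0); e1 <- exp(x1)
  z <- e0 + e1 + 1
  p0 <- e0 / z; p1 <- e1 / z; p2 <- 1 - p0 - p1
  c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
}

bs_class_spec <- function(w0, w2) {
  # rows: class 0, 1, 2a, 2b; columns: background / foreground omega
  cbind(bg = c(w0, 1, w0, 1), fg = c(w0, 1, w2, w2))
}

#' Branch-site test of positive selection on a foreground branch
#'
#' Fits branch-site model A: four site classes with background omega in
#' {omega0, 1} and a foreground class allowing omega2 >= 1 on the marked
#' branch only. The null fixes omega2 = 1; the alternative frees it, is
#' initialized at the null optimum (so lnL_alt >= lnL_null) plus a
#' deterministic omega2 multistart over {1.5, 5}, and the LRT statistic
#' 2(lnL_alt - lnL_null), clamped at zero, is referred to chi-square with
#' one degree of freedom (the conservative choice relative to the 50:50
#' boundary mixture). Branch lengths are taken from the input tree.
#'
#' @param aln codon alignment covering the tree tips.
#' @param tree `phylo` tree with branch lengths.
#' @param foreground tip label of the foreground branch; defaults to the
#'   `#1`-marked tip of `tree`.
#' @param pi codon frequencies or `NULL` for uniform.
#' @param code genetic code.
#' @return List with `lnL_null`, `lnL_alt`, `statistic`, `df`, `p`,
#'   `params` (alternative-model estimates: `kappa`, `p0`, `p1`, `p2a`,
#'   `p2b`, `omega0`, `omega2`) and `convergence`.
#' @export
fit_branch_site <- function(aln, tree, foreground = NULL, pi = NULL,
                            code = genetic_code()) {
  if (is.null(foreground)) foreground <- foreground_tip(tree)
  if (is.na(foreground)) stop("no foreground branch marked or given")
  edges <- tree_edges(tree)
  if (any(is.na(edges$length))) stop("tree must have branch lengths")
  fg <- foreground_edge(edges, foreground)
  patterns <- aln_patterns(aln[intersect(names(aln), edges$label)], code)
  pi <- check_codon_freqs(pi, length(sense_codons(code)))
  n_edge <- nrow(edges$edge)
  t <- edges$length

  omega_matrix <- function(w0, w2) {
    spec <- bs_class_spec(w0, w2)
    m <- matrix(rep(spec[, "bg"], n_edge), nrow = 4L)
    m[, fg] <- spec[, "fg"]
    m
  }
  negll <- function(kappa, x0, x1, w0, w2) {
    -mixture_loglik(patterns, edges, kappa, pi, omega_matrix(w0, w2),
                    bs_props(x0, x1), t, code,
                    scale_omegas = bs_class_spec(w0, w2)[, "bg"])
  }
  # null: par = (log kappa, x0, x1, logit omega0)
  null_obj <- function(par) {
    negll(exp(par[1L]), par[2L], par[3L], stats::plogis(par[4L]), 1)
  }
  null_fit <- stats::nlminb(c(log(2), 1, 0, stats::qlogis(0.2)), null_obj,
                            lower = c(log(1e-2), -15, -15, -15),
                            upper = c(log(100), 15, 15, 15),
                            control = list(rel.tol = 1e-9, iter.max = 300))
  # alternative: add log(omega2 - 1); start at the null optimum and at a
  # deterministic multistart over omega2
  alt_obj <- function(par) {
    negll(exp(par[1L]), par[2L], par[3L], stats::plogis(par[4L]),
          1 + exp(par[5L]))
  }
  alt_best <- NULL
  for (w2_0 in c(1 + 1e-6, 1.5, 5)) {
    fit <- stats::nlminb(c(null_fit$par, log(w2_0 - 1)), alt_obj,
                         lower = c(log(1e-2), -15, -15, -15, log(1e-8)),
                         upper = c(log(100), 15, 15, 15, log(98)),
                         control = list(rel.tol = 1e-9, iter.max = 300))
    if (is.null(alt_best) || fit$objective < alt_best$objective - 1e-9) {
      alt_best <- fit
    }
  }
  lnL_null <- -null_fit$objective
  lnL_alt <- max(-alt_best$objective, lnL_null)
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  props <- bs_props(alt_best$par[2L], alt_best$par[3L])
  list(
    lnL_null = lnL_null, lnL_alt = lnL_alt,
    statistic = stat, df = 1L,
    p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    params = c(kappa = exp(alt_best$par[1L]),
               p0 = props[1L], p1 = props[2L],
               p2a = props[3L], p2b = props[4L],
               omega0 = stats::plogis(alt_best$par[4L]),
               omega2 = 1 + exp(alt_best$par[5L])),
    convergence = null_fit$convergence %in% c(0L, 1L) &&
      alt_best$convergence %in% c(0L, 1L)
  )
}

#' Scan a gene set for positively selected genes
#'
#' Runs the branch-site LRT of [fit_branch_site()] on every gene, applies
#' Benjamini-Hochberg FDR control across the family, and calls a gene a
#' positively selected gene (PSG) when its adjusted p-value falls below the
#' cutoff. Genes with fewer than `min_codons` comparable codon columns are
#' excluded to avoid degenerate likelihood ratio tests; genes whose fits
#' fail to converge are excluded from the FDR family and flagged.
#'
#' @param alns named list of codon alignments (one per gene).
#' @param tree `phylo` tree with branch lengths shared by all genes.
#' @param foreground foreground tip label (default: the marked tip).
#' @param fdr_cutoff PSG significance threshold on the BH-adjusted p-value
#'   (default 0.05).
#' @param min_codons minimum comparable codons per gene (default 50).
#' @param pi,code see [fit_branch_site()].
#' @return `data.frame` with one row per tested gene: `gene`, `lnL_null`,
#'   `lnL_alt`, `statistic`, `p`, `q`, `omega2`, `psg`; excluded genes are
#'   reported in the `excluded` attribute.
#' @export
psg_scan <- function(alns, tree, foreground = NULL, fdr_cutoff = 0.05,
                     min_codons = 50L, pi = NULL, code = genetic_code()) {
  if (is.null(names(alns))) names(alns) <- paste0("gene", seq_along(alns))
  rows <- list()
  excluded <- character(0)
  for (g in names(alns)) {
    cleaned <- clean_codon_columns(alns[[g]], code)
    if (nchar(cleaned[[1L]]) / 3 < min_codons) {
      excluded <- c(excluded, g)
      next
    }
    fit <- tryCatch(
      fit_branch_site(alns[[g]], tree, foreground, pi, code),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$convergence) {
      excluded <- c(excluded, g)
      next
    }
    rows[[g]] <- data.frame(
      gene = g, lnL_null = fit$lnL_null, lnL_alt = fit$lnL_alt,
      statistic = fit$statistic, p = fit$p,
      omega2 = fit$params[["omega2"]], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), lnL_null = numeric(0),
                      lnL_alt = numeric(0), statistic = numeric(0),
                      p = numeric(0), omega2 = numeric(0))
  }
  out$q <- bh_fdr(out$p)
  out$psg <- out$q < fdr_cutoff
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
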