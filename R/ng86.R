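#' Nei-Gojobori (1986) counting estimator of Ka and Ks
#'
#' The NG86 method counts, for each codon, the fractional numbers of
#' synonymous (s) and nonsynonymous (n) sites among its nine single-base
#' mutants, and classifies observed codon differences by averaging over all
#' orderings of the single-step mutational pathways between the two codons.
#' Proportions of differences per site are then corrected for multiple hits
#' with the Jukes-Cantor formula d = -(3/4) log(1 - 4p/3).
#'
#' @name ng86
NULL

.ng86_cache <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

codon_neighbours <- function(codon) {
  out <- character(0)
  ch <- strsplit(codon, "")[[1L]]
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, ch[pos])) {
      mut <- ch
      mut[pos] <- nt
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts for one codon
#'
#' @param codon sense codon (3 upper-case ACGT letters).
#' @param code genetic code.
#' @param stop_mutations `"nonsynonymous"` (the original NG86 convention:
#'   single-base mutations to stop codons count as nonsynonymous, so
#'   `s + n = 3`) or `"exclude"` (stop neighbours are dropped from the site
#'   total, so `s + n <= 3`).
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @export
ng86_site_counts <- function(codon, code = genetic_code(),
                             stop_mutations = c("nonsynonymous", "exclude")) {
  stop_mutations <- match.arg(stop_mutations)
  aa <- code[codon]
  if (is.na(aa)) stop("'", codon, "' is not an unambiguous codon")
  if (aa == "*") stop("'", codon, "' is a stop codon")
  neigh <- codon_neighbours(codon)
  aa_n <- code[neigh]
  syn <- sum(aa_n == aa & aa_n != "*") / 3
  if (stop_mutations == "nonsynonymous") {
    n <- 3 - syn
  } else {
    n <- sum(aa_n != aa & aa_n != "*") / 3
  }
  c(s = syn, n = n)
}

# All orderings of the differing positions, as a list of integer vectors.
.orderings <- function(pos) {
  k <- length(pos)
  if (k == 1L) return(list(pos))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in .orderings(pos[-i])) out <- c(out, list(c(pos[i], rest)))
  }
  out
}

#' Pathway-averaged synonymous/nonsynonymous difference counts
#'
#' For codons differing at k positions, every one of the k! orderings of
#' single-base steps is walked; orderings passing through a stop codon are
#' excluded and the synonymous/nonsynonymous step classifications of the
#' remaining pathways are averaged. If every pathway passes through a stop,
#' all k differences are counted as nonsynonymous, with a warning.
#'
#' @param codon_a,codon_b sense codons.
#' @param code genetic code.
#' @return Named numeric vector `c(sd = ..., nd = ...)` with `sd + nd`
#'   equal to the Hamming distance of the codons.
#' @export
ng86_diff_counts <- function(codon_a, codon_b, code = genetic_code()) {
  for (cod in c(codon_a, codon_b)) {
    aa <- code[cod]
    if (is.na(aa)) stop("'", cod, "' is not an unambiguous codon")
    if (aa == "*") stop("'", cod, "' is a stop codon")
  }
  a <- strsplit(codon_a, "")[[1L]]
  b <- strsplit(codon_b, "")[[1L]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths_sd <- numeric(0)
  paths_nd <- numeric(0)
  for (ord in .orderings(pos)) {
    cur <- a
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- code[paste(cur, collapse = "")]
      aa2 <- code[paste(nxt, collapse = "")]
      if (aa2 == "*") {
        ok <- FALSE
        break
      }
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      paths_sd <- c(paths_sd, sd)
      paths_nd <- c(paths_nd, nd)
    }
  }
  if (length(paths_sd) == 0L) {
    warning("all mutational pathways between ", codon_a, " and ", codon_b,
            " pass through a stop codon; counting all ", k,
            " differences as nonsynonymous")
    return(c(sd = 0, nd = k))
  }
  c(sd = mean(paths_sd), nd = mean(paths_nd))
}

# Lookup tables over the 61 sense codons, built once per (code, convention).
ng86_tables <- function(code = genetic_code(),
                        stop_mutations = "nonsynonymous") {
  key <- paste0(paste(code, collapse = ""), "|", stop_mutations)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  cods <- sense_codons(code)
  sites <- t(vapply(cods, ng86_site_counts, numeric(2L),
                    code = code, stop_mutations = stop_mutations))
  n <- length(cods)
  sd <- matrix(0, n, n, dimnames = list(cods, cods))
  nd <- matrix(0, n, n, dimnames = list(cods, cods))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- suppressWarnings(ng86_diff_counts(cods[i], cods[j], code))
        sd[i, j] <- sd[j, i] <- d[["sd"]]
        nd[i, j] <- nd[j, i] <- d[["nd"]]
      }
    }
  }
  tab <- list(codons = cods, sites = sites, sd = sd, nd = nd)
  .ng86_cache[[key]] <- tab
  tab
}

#' NG86 Ka/Ks for a two-sequence codon alignment
#'
#' Site totals are averaged over the two sequences; substitution counts are
#' pathway-averaged sums over codon columns; rates are Jukes-Cantor
#' corrected proportions. Codon columns containing gaps, ambiguity codes or
#' stops are removed first (complete deletion).
#'
#' @param aln codon alignment with exactly two rows (or a length-2 named
#'   character vector).
#' @param code genetic code.
#' @param stop_mutations see [ng86_site_counts()].
#' @return One-row `data.frame` with columns `pair`, `n_codons`, `S_sites`,
#'   `N_sites`, `S_subs` (the synonymous substitution count, the pooled "S"
#'   statistic), `A_subs` (nonsynonymous, "A"), `pS`, `pN`, `Ks`, `Ka`,
#'   `omega`, `method`, `valid`. `omega` is `NA` with `valid = FALSE` when
#'   `Ks` is zero or a Jukes-Cantor correction saturates (p >= 3/4).
#' @export
kaks_ng86 <- function(aln, code = genetic_code(),
                      stop_mutations = "nonsynonymous") {
  aln <- codon_alignment(aln)
  if (length(aln) != 2L) stop("NG86 estimation needs exactly two sequences")
  aln <- clean_codon_columns(aln, code)
  m <- codon_matrix(aln)
  nc <- ncol(m)
  if (nc < 1L) stop("no comparable codon columns between the two sequences")
  tab <- ng86_tables(code, stop_mutations)
  i1 <- match(m[1L, ], tab$codons)
  i2 <- match(m[2L, ], tab$codons)
  S_sites <- (sum(tab$sites[i1, "s"]) + sum(tab$sites[i2, "s"])) / 2
  N_sites <- (sum(tab$sites[i1, "n"]) + sum(tab$sites[i2, "n"])) / 2
  idx <- cbind(i1, i2)
  S_subs <- sum(tab$sd[idx])
  A_subs <- sum(tab$nd[idx])
  pS <- if (S_sites > 0) S_subs / S_sites else NA_real_
  pN <- if (N_sites > 0) A_subs / N_sites else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS)
  Ka <- jc(pN)
  valid <- !is.na(Ks) && !is.na(Ka) && Ks > 0
  omega <- if (valid) Ka / Ks else NA_real_
  data.frame(
    pair = paste(names(aln), collapse = ":"),
    n_codons = nc, S_sites = S_sites, N_sites = N_sites,
    S_subs = S_subs, A_subs = A_subs, pS = pS, pN = pN,
    Ks = Ks, Ka = Ka, omega = omega,
    method = "NG86", valid = valid,
    stringsAsFactors = FALSE
  )
}
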