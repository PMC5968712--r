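#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; `NA` inputs stay `NA`
#' and do not count towards the family size.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, monotone in the ranking of `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pooled-count Fisher test of accelerated evolution
#'
#' Compares the substitution spectrum of a gene category between two
#' species pairs through the 2x2 table of pooled nonsynonymous (A) and
#' synonymous (S) substitution counts, one row per species pair. The
#' two-sided p-value sums all hypergeometric outcomes no more probable than
#' the observed table.
#'
#' @param A1,S1 pooled nonsynonymous and synonymous counts in species
#'   pair 1.
#' @param A2,S2 the same for species pair 2.
#' @return Named list with `odds` (the sample odds ratio `(A1 S2)/(S1 A2)`,
#'   possibly 0 or `Inf`), `p`, and `flagged` (`TRUE` for an all-zero
#'   table, reported as p = 1).
#' @export
fisher_acceleration_test <- function(A1, S1, A2, S2) {
  counts <- c(A1, S1, A2, S2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("pooled substitution counts must be non-negative integers")
  }
  if (sum(counts) == 0) {
    return(list(odds = NA_real_, p = 1, flagged = TRUE))
  }
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  odds <- if (S1 == 0 || A2 == 0) {
    if (A1 == 0 || S2 == 0) NA_real_ else Inf
  } else {
    (A1 * S2) / (S1 * A2)
  }
  list(odds = odds, p = min(p, 1), flagged = FALSE)
}

#' Two-tailed binomial sign test
#'
#' Exact two-tailed test of the counts of genes evolving faster in one
#' species pair versus the other, under the null of equal probability 1/2.
#' Ties must already be excluded. The two-tailed p sums all outcomes whose
#' point probability does not exceed that of the observed count.
#'
#' @param n_higher_1,n_higher_2 non-negative integer counts.
#' @return List with `p` and `flagged` (`TRUE` when both counts are zero).
#' @export
binomial_sign_test <- function(n_higher_1, n_higher_2) {
  if (n_higher_1 < 0 || n_higher_2 < 0) stop("counts must be non-negative")
  n <- n_higher_1 + n_higher_2
  if (n == 0) return(list(p = 1, flagged = TRUE))
  p <- stats::binom.test(n_higher_1, n, p = 0.5,
                         alternative = "two.sided")$p.value
  list(p = min(p, 1), flagged = FALSE)
}

#' Paired Wilcoxon signed-rank test on per-gene omega values
#'
#' Genes with an undefined ratio in either pair and zero differences are
#' dropped; the remaining differences go through the exact signed-rank null
#' for n <= 25 and the normal approximation with continuity correction
#' above (the standard [stats::wilcox.test()] behavior; ties force the
#' approximation).
#'
#' @param omega1,omega2 paired per-gene values.
#' @return List with `statistic` (V), `p`, `n` used, and `flagged` (`TRUE`
#'   when no informative pair remains, reported as p = 1).
#' @export
wilcoxon_paired_test <- function(omega1, omega2) {
  keep <- is.finite(omega1) & is.finite(omega2)
  d <- omega1[keep] - omega2[keep]
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(list(statistic = NA_real_, p = 1, n = 0L, flagged = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = length(d) <= 25L, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = length(d), flagged = FALSE)
}

#' Flag the top decile of categories by mean omega
#'
#' @param category ids, one per category.
#' @param mean_omega mean Ka/Ks per category (NA allowed; never flagged).
#' @param fraction decile fraction (default 0.1); the top
#'   `ceiling(fraction * m)` categories are flagged, ties broken by
#'   category id.
#' @return Logical vector parallel to `category`.
#' @export
rank_top_decile <- function(category, mean_omega, fraction = 0.1) {
  m <- length(category)
  if (m == 0L) stop("at least one category is required")
  k <- ceiling(fraction * m)
  ord <- order(-mean_omega, category, na.last = TRUE)
  flagged <- logical(m)
  top <- ord[seq_len(k)]
  flagged[top] <- is.finite(mean_omega[top])
  flagged
}

#' Per-category aggregation of two species pairs' Ka/Ks estimates
#'
#' Joins two per-gene Ka/Ks tables on a shared ortholog id, groups genes by
#' functional category, and computes per-category averages and pooled
#' substitution counts for both species pairs. "Average Ka/Ks" is the mean
#' of per-gene ratios over genes with a defined ratio (the default); the
#' pooled-ratio alternative `(sum Ka)/(sum Ks)` is also reported since
#' per-gene averaging is sensitive to near-zero Ks genes. Pooled A and S
#' counts are rounded half-away-from-zero to integers so the exact test
#' applies.
#'
#' @param est1,est2 per-gene estimate data.frames (from [kaks_ng86()] /
#'   [kaks_ml()] rows) with a `gene` column shared across pairs.
#' @param annotation data.frame with columns `gene`, `category`.
#' @param min_genes minimum paired genes per category (default 5).
#' @return `data.frame`, one row per retained category, with averages,
#'   pooled counts, and the Fisher / binomial sign / Wilcoxon test results,
#'   each FDR-corrected within its own test family, plus a `top_decile`
#'   flag from the pair-1 mean omega.
#' @export
aggregate_by_category <- function(est1, est2, annotation, min_genes = 5L) {
  if (nrow(annotation) == 0L) stop("empty annotation table")
  for (nm in c("gene", "category")) {
    if (!nm %in% names(annotation)) stop("annotation lacks column '", nm, "'")
  }
  merged <- merge(est1, est2, by = "gene", suffixes = c("_1", "_2"))
  merged <- merge(merged, annotation, by = "gene")
  if (nrow(merged) == 0L) stop("no annotated genes shared between the pairs")
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  rows <- lapply(split(merged, merged$category), function(d) {
    if (nrow(d) < min_genes) return(NULL)
    valid1 <- is.finite(d$omega_1)
    valid2 <- is.finite(d$omega_2)
    A1 <- half_away(sum(d$A_subs_1)); S1 <- half_away(sum(d$S_subs_1))
    A2 <- half_away(sum(d$A_subs_2)); S2 <- half_away(sum(d$S_subs_2))
    fis <- fisher_acceleration_test(A1, S1, A2, S2)
    both <- valid1 & valid2
    n_higher_1 <- sum(both & d$omega_1 > d$omega_2)
    n_higher_2 <- sum(both & d$omega_2 > d$omega_1)
    n_ties <- sum(both) - n_higher_1 - n_higher_2
    bin <- binomial_sign_test(n_higher_1, n_higher_2)
    wil <- wilcoxon_paired_test(d$omega_1, d$omega_2)
    data.frame(
      category = d$category[1L], n_genes = nrow(d),
      mean_Ka_1 = mean(d$Ka_1), mean_Ks_1 = mean(d$Ks_1),
      mean_omega_1 = if (any(valid1)) mean(d$omega_1[valid1]) else NA_real_,
      pooled_omega_1 = pooled_ratio(d$Ka_1, d$Ks_1),
      mean_Ka_2 = mean(d$Ka_2), mean_Ks_2 = mean(d$Ks_2),
      mean_omega_2 = if (any(valid2)) mean(d$omega_2[valid2]) else NA_real_,
      pooled_omega_2 = pooled_ratio(d$Ka_2, d$Ks_2),
      A1 = A1, S1 = S1, A2 = A2, S2 = S2,
      fisher_odds = fis$odds, fisher_p = fis$p,
      n_higher_1 = n_higher_1, n_higher_2 = n_higher_2, n_ties = n_ties,
      binomial_p = bin$p,
      wilcoxon_stat = if (is.na(wil$statistic)) NA_real_ else wil$statistic,
      wilcoxon_p = wil$p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no category passed the min_genes filter")
  out$fisher_q <- bh_fdr(out$fisher_p)
  out$binomial_q <- bh_fdr(out$binomial_p)
  out$wilcoxon_q <- bh_fdr(out$wilcoxon_p)
  out$top_decile <- rank_top_decile(out$category, out$mean_omega_1)
  rownames(out) <- NULL
  out
}

pooled_ratio <- function(Ka, Ks) {
  ka <- sum(Ka[is.finite(Ka)])
  ks <- sum(Ks[is.finite(Ks)])
  if (ks > 0) ka / ks else NA_real_
}
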