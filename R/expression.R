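#' Counts per million
#'
#' @param counts genes-by-samples count matrix.
#' @param lib.sizes per-sample library sizes; defaults to the `lib.sizes`
#'   attribute of `counts`, else column sums.
#' @return Numeric matrix of CPM values.
#' @export
cpm_matrix <- function(counts, lib.sizes = NULL) {
  if (is.null(lib.sizes)) lib.sizes <- attr(counts, "lib.sizes")
  if (is.null(lib.sizes)) lib.sizes <- colSums(counts)
  if (any(lib.sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, lib.sizes, "/") * 1e6
}

#' Expression filter: minimum CPM in every sample
#'
#' A gene is retained only when its CPM reaches the threshold in every
#' sample ("less than threshold in any sample" excludes it).
#'
#' @param counts genes-by-samples count matrix.
#' @param threshold minimum CPM (default 10).
#' @param lib.sizes see [cpm_matrix()].
#' @return Character vector of retained gene ids.
#' @export
filter_min_cpm <- function(counts, threshold = 10, lib.sizes = NULL) {
  if (threshold < 0) stop("threshold must be non-negative")
  cpm <- cpm_matrix(counts, lib.sizes)
  rownames(counts)[apply(cpm >= threshold, 1L, all)]
}

#' Fixed-dispersion negative-binomial exact test for two samples
#'
#' The no-replicate exact test: both counts are rescaled to the geometric
#' mean of the two library sizes (rounded half-to-even), and, conditional
#' on the rescaled total, the two-sided p-value sums the probabilities of
#' all splits no more probable than the observed one under independent
#' NB(mean, dispersion) counts with a common mean. With dispersion 0 the
#' test reduces to the conditional binomial (Poisson) exact test. The
#' dispersion is a required a-priori parameter - with single samples it
#' cannot be estimated from the data.
#'
#' @param count_a,count_b observed counts (scalars or parallel vectors).
#' @param libsize_a,libsize_b library sizes.
#' @param dispersion negative-binomial dispersion phi >= 0 (variance =
#'   mu + phi mu^2).
#' @return Numeric vector of two-sided p-values.
#' @export
nb_exact_test <- function(count_a, count_b, libsize_a, libsize_b,
                          dispersion) {
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (libsize_a <= 0 || libsize_b <= 0) stop("library sizes must be positive")
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n)
  count_b <- rep_len(count_b, n)
  g <- sqrt(libsize_a * libsize_b)
  ya <- round(count_a * g / libsize_a)
  yb <- round(count_b * g / libsize_b)
  vapply(seq_len(n), function(i) {
    tot <- ya[i] + yb[i]
    if (tot == 0) return(1)
    k <- 0:tot
    logp <- if (dispersion == 0) {
      stats::dpois(k, tot / 2, log = TRUE) +
        stats::dpois(tot - k, tot / 2, log = TRUE)
    } else {
      size <- 1 / dispersion
      stats::dnbinom(k, size = size, mu = tot / 2, log = TRUE) +
        stats::dnbinom(tot - k, size = size, mu = tot / 2, log = TRUE)
    }
    logp <- logp - max(logp)
    pr <- exp(logp)
    obs <- pr[ya[i] + 1L]
    min(1, sum(pr[pr <= obs * (1 + 1e-10)]) / sum(pr))
  }, numeric(1L))
}

#' Direction calls from exact-test results
#'
#' @param p per-gene p-values.
#' @param log_fc per-gene log2 fold changes (sample B over sample A).
#' @param fdr_cutoff BH-adjusted significance threshold (default 0.01).
#' @return `data.frame` with `p`, `q`, `log2_fc`, and `direction` in
#'   `{"up", "down", "ns"}` (direction is assigned only under the cutoff).
#' @export
de_call <- function(p, log_fc, fdr_cutoff = 0.01) {
  q <- bh_fdr(p)
  direction <- rep("ns", length(p))
  sig <- !is.na(q) & q < fdr_cutoff
  direction[sig & log_fc > 0] <- "up"
  direction[sig & log_fc < 0] <- "down"
  data.frame(p = p, q = q, log2_fc = log_fc, direction = direction,
             stringsAsFactors = FALSE)
}

#' Shared direction calls between two comparisons
#'
#' @param calls1,calls2 data.frames with `gene` and `direction` columns.
#' @return List with `up` and `down`: gene ids called in the same
#'   direction in both comparisons.
#' @export
intersect_calls <- function(calls1, calls2) {
  shared <- function(dir) {
    intersect(calls1$gene[calls1$direction == dir],
              calls2$gene[calls2$direction == dir])
  }
  list(up = shared("up"), down = shared("down"))
}

#' Two-sample differential expression without replicates
#'
#' CPM filtering across all samples of the matrix, then the
#' fixed-dispersion exact test between the two named samples, BH
#' correction, and direction calls. Fold changes are computed on CPM with
#' a 0.5-count offset to keep zero counts finite.
#'
#' @param counts genes-by-samples count matrix.
#' @param sample_a,sample_b column names to compare; the fold change is
#'   `sample_a` over `sample_b`.
#' @param dispersion a-priori NB dispersion (default 0.2, a deliberately
#'   conservative single-sample setting).
#' @param min_cpm CPM filter threshold applied across every column of
#'   `counts` (default 10).
#' @param fdr_cutoff call threshold on the adjusted p (default 0.01).
#' @param lib.sizes see [cpm_matrix()].
#' @return `data.frame` with one row per retained gene: `gene`, counts,
#'   CPM, `log2_fc`, `p`, `q`, `direction`.
#' @export
dge_exact <- function(counts, sample_a, sample_b, dispersion = 0.2,
                      min_cpm = 10, fdr_cutoff = 0.01, lib.sizes = NULL) {
  if (is.null(lib.sizes)) lib.sizes <- attr(counts, "lib.sizes")
  if (is.null(lib.sizes)) lib.sizes <- colSums(counts)
  if (is.null(names(lib.sizes))) names(lib.sizes) <- colnames(counts)
  for (s in c(sample_a, sample_b)) {
    if (!s %in% colnames(counts)) stop("no sample column '", s, "'")
  }
  keep <- filter_min_cpm(counts, min_cpm, lib.sizes)
  if (length(keep) == 0L) stop("no gene passes the CPM filter")
  ca <- counts[keep, sample_a]
  cb <- counts[keep, sample_b]
  la <- lib.sizes[[sample_a]]
  lb <- lib.sizes[[sample_b]]
  p <- nb_exact_test(ca, cb, la, lb, dispersion)
  log_fc <- log2((ca + 0.5) / la) - log2((cb + 0.5) / lb)
  calls <- de_call(p, log_fc, fdr_cutoff)
  cbind(data.frame(gene = keep, count_a = ca, count_b = cb,
                   cpm_a = ca / la * 1e6, cpm_b = cb / lb * 1e6,
                   stringsAsFactors = FALSE),
        calls)
}
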