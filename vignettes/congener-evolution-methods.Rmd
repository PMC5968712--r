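---
title: "Models and methods for comparative congener evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for comparative congener evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This package implements the comparative molecular-evolution and expression
workflow used to contrast an invasive plant with closely related
non-invasive congeners: which functional classes of genes evolve faster
between the invasive and non-invasive lineages, which individual genes show
branch-specific positive selection, and which genes are differentially
expressed when only one RNA-seq sample per species exists. This vignette
records the models, the tunable parameters, the numerical choices, and the
limits of what the test suite demonstrates.

## Ortholog pairing and codon alignments

Orthologs between two species are taken as reciprocal best hits (RBH): gene
*x* is paired with *y* only when *y* is the unique top-scoring match of *x*
and vice versa. Scores can come from an external similarity search in
12-column tabular format, or from the built-in Needleman–Wunsch global
aligner (BLOSUM62, gap open 10, gap extend 0.5 via
`Biostrings::pairwiseAlignment()`), which removes any external-binary
dependency at desk scale. A tied best hit is treated as absence of
one-to-one orthology and excludes the gene, with a warning; no tie-breaking
heuristic is attempted. Across *k* species, single-copy groups are the RBH
cliques: one gene per species with every cross-species pair reciprocal-best.

Protein alignments are back-translated codon-by-codon onto the coding
sequences (`backtranslate_alignment()`), so gaps always occupy whole codons.
Before any rate estimation, codon columns containing a gap, an ambiguity
code, or a stop in any row are removed (complete deletion), mirroring the
usual "cleandata" practice. All coordinates are 0-based half-open
internally; a codon index is a nucleotide index divided by three.

## Pairwise Ka/Ks

Two estimators are exposed through one interface:

* **NG86 counting** (`kaks_ng86()`), the deterministic reference. Per
  codon, fractional synonymous site counts come from the nine single-base
  mutants; differences between codons are classified by averaging over all
  orderings of single-step pathways, skipping pathways through stops; the
  per-site proportions are Jukes–Cantor corrected,
  $d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$. Mutations *to* stop codons
  count as nonsynonymous sites by default (the original convention, so
  $s + n = 3$ per codon); `stop_mutations = "exclude"` drops them instead.
  The default is the published convention, but note that a generator which
  forbids mutations to stops (as ours does, and as real coding evolution
  effectively does) is matched by the *exclude* convention: with the
  default, ~4% of the mutational opportunity assigned to nonsynonymous
  sites can never be realized, which depresses Ka/Ks by roughly 5% even
  with equal transition and transversion rates. NG86 also ignores the
  transition/transversion ratio entirely: at $\kappa = 2$ it underestimates
  a true $\omega = 1$ by roughly 15%. These are properties of the
  estimator, not implementation artifacts; the maximum-likelihood estimator
  below is free of both.

* **GY94 maximum likelihood** (`kaks_ml()`). The two-sequence
  log-likelihood $\sum_{\text{sites}} \log \pi_i P_{ij}(t)$ is maximized
  over $(t, \kappa, \omega)$ by bounded quasi-Newton with a deterministic
  multistart over $t \in \{0.01, 0.1, 0.5\}$. Codon frequencies are F3x4
  (positional nucleotide frequencies of the pair, stops zeroed and
  renormalized) or uniform. The fitted divergence is decomposed as
  $K_a = t\,\rho_N / (3 f_N)$ and $K_s = t\,\rho_S / (3 f_S)$, where
  $\rho$ are the nonsynonymous/synonymous flux fractions of the fitted
  generator and $f$ the same fractions at $\omega = 1$; this reproduces
  the standard codeml decomposition and guarantees $K_a/K_s = \omega$.

When $K_s = 0$ or a Jukes–Cantor correction saturates ($p \ge 3/4$), the
ratio is reported as undefined and the gene is excluded from per-category
ratio averaging; pooled substitution-count tests are unaffected because
they use the counts, not the ratios.

## Category-level acceleration tests

Per functional category (GO term or pathway), genes annotated to the
category and estimated in both species pairs are aggregated
(`aggregate_by_category()`; categories with fewer than 5 such genes are
dropped — the floor is a package default, chosen so pooled 2×2 tables have
some mass). Three complementary tests are run, each BH-corrected within its
own family:

1. **Pooled-count Fisher test**: the 2×2 table of pooled nonsynonymous (A)
   and synonymous (S) substitution counts, one row per species pair;
   two-sided exact p. Real-valued (pathway-averaged or ML-expected) counts
   are rounded half-away-from-zero first.
2. **Binomial sign test** on the per-gene direction of the ratio
   difference, ties excluded, exact and two-tailed.
3. **Wilcoxon signed-rank test** on the paired per-gene ratios (exact null
   for n ≤ 25 without ties, normal approximation with continuity
   correction otherwise).

"Average Ka/Ks" of a category is ambiguous between the mean of per-gene
ratios and the ratio of pooled rates; both are reported
(`mean_omega_*`, `pooled_omega_*`). The mean-of-ratios is the primary
column because only it can reproduce category averages far above 1, which
arise when individual genes with near-zero $K_s$ dominate; the pooled form
is robust to exactly that. The fastest-evolving decile
(`rank_top_decile()`) flags the top $\lceil 0.1 m \rceil$ categories by
primary mean ratio, ties broken by category id. Annotations are used as
given — GO ancestor propagation, if wanted, is a pre-processing step left
to the caller.

## Codon models on trees

The GY94 generator has $q_{ij} \propto \pi_j \kappa^{[\text{ts}]}
\omega^{[\text{nonsyn}]}$ for single-nucleotide changes. Likelihoods come
from Felsenstein pruning over the 61 sense-codon states with site-pattern
compression; ambiguous codons are missing data. Because the generator is
reversible it is diagonalized once per distinct $\omega$ through the
symmetrized form $\Pi^{1/2} Q \Pi^{-1/2}$, and $P(t)$ is assembled from the
eigendecomposition for every branch length — the dominant cost of all tree
fits.

**Normalization.** With a single site class, each branch's generator is
scaled so one branch-length unit is one expected substitution per codon on
that branch (free-ratio convention; with branch lengths free this is only a
parameterization). With site-class mixtures the classes must share one
clock, otherwise a fast class cannot generate excess divergence and a
branch-site test loses essentially all power: the common scale is the mean
rate of the background mixture, which is also exactly how the simulator
advances time.

* **Free-ratio model** (`fit_free_ratio()`): independent $(t_b, \omega_b)$
  per branch plus a shared $\kappa$, bounded in $t \in [10^{-4}, 50]$,
  $\omega \in [10^{-4}, 99]$, deterministic $\omega$ multistart
  $\{0.3, 1\}$. Per-branch Ka/Ks use the same flux decomposition as the
  pairwise ML. Lineage summaries use the **median** across genes
  (`lineage_median()`), which is robust to the extreme ratios of
  near-zero-$K_s$ genes; invalid ratios are excluded.

* **Branch-site model A** (`fit_branch_site()`): four site classes with
  background $\omega \in \{\omega_0, 1\}$ and foreground $\omega_2 \ge 1$
  on one marked branch, proportions constrained as
  $p_{2a} : p_{2b} = p_0 : p_1$. The null fixes $\omega_2 = 1$. The
  alternative starts at the null optimum (guaranteeing
  $\ln L_{alt} \ge \ln L_{null}$) plus a deterministic multistart
  $\omega_2 \in \{1.5, 5\}$. The LRT statistic is clamped at zero and
  referred to $\chi^2_1$ — conservative relative to the 50:50 boundary
  mixture, and the common practice. Branch lengths are taken from the
  input tree rather than re-estimated per gene: at desk scale this is the
  dominant runtime saving, and with trees estimated from concatenated data
  it matches how genome-scale scans are usually run. Genes with fewer
  than 50 comparable codons are excluded from scans
  (`psg_scan()`) to avoid degenerate tests; positive selection is called
  at BH-FDR < 0.05 across the scanned family.

## Differential expression without replicates

Counts are CPM-filtered (a gene must reach `min_cpm`, default 10, in
*every* sample of the matrix), then tested pairwise with a
fixed-dispersion negative-binomial exact test (`nb_exact_test()`): counts
are rescaled to the geometric mean of the two library sizes (rounded
half-to-even — a documented simplification of edgeR's quantile
adjustment), and, conditional on the rescaled total, the two-sided p sums
the probabilities of all splits no more probable than the observed one.
At dispersion 0 this is exactly the conditional binomial (Poisson) test.
The dispersion is a required a-priori parameter, defaulting to the
deliberately conservative 0.2 — with one sample per condition it cannot be
estimated, and a conservative value is the honest choice. No TMM-style
normalization is applied by default.

The conservatism has a quantifiable price: the conditional log-ratio noise
is about $\sqrt{2\phi}$ (≈ 0.63 at $\phi = 0.2$) independent of counts, so
the smallest fold change that can clear a BH-FDR of 0.01 is roughly
$e^{3.4\sqrt{2\phi}} \approx 8.5$. Four-fold changes are invisible at this
setting no matter how deeply sequenced — a floor worth knowing when
interpreting both real results and recovery experiments. Direction calls
(`de_call()`) are made only below the FDR cutoff (default 0.01), and
shared calls across two comparisons require matching direction
(`intersect_calls()`).

## Enrichment

Gene-set enrichment (`fisher_enrichment()`) uses the one-tailed
(over-representation) Fisher exact test over the annotated-gene universe —
the population defaults to annotated genes because category contents are
only comparable within the annotated universe — with BH correction;
`enriched` requires q < 0.05 and odds ratio > 1. Species-content
comparison (`compare_species_categories()`) is two-sided, since either
species may over-represent a category, and records the direction.

## The simulator

`simulate_alignment()` evolves each codon independently by exact
stochastic jumps (Gillespie) along each branch: the root codon is drawn
from the stationary frequencies, waiting times are exponential with the
codon's total exit rate, and jumps are drawn from the embedded chain. This
costs more than sampling from $P(t)$ but yields *realized* substitution
counts per branch, which is what makes counting-method oracles and
law-of-large-numbers checks possible. Time is scaled so one branch-length
unit is one expected substitution per codon under the gene-average
background model; branch-omega overrides and foreground site classes
therefore change realized divergence, exactly like their inference-side
counterparts. One global seed is split into per-gene seeds up front, so
gene order cannot affect any gene's data.

`simulate_family_set()` assigns genes round-robin to categories and
multiplies the foreground-branch omega of genes in accelerated categories.
`simulate_counts()` draws NB counts with log-normal baseline expression
across genes and plants signed log2 fold changes in a chosen sample.

What the simulator does **not** emulate: indels and alignment error,
within-species polymorphism, rate variation beyond discrete site classes,
assembly artifacts, GC-biased gene conversion, and correlated expression
between genes. Passing recovery tests therefore demonstrates correctness
of the estimators under their own model class, not robustness to real
transcriptome noise.

## Study-scale choices and test design

The default study tree (`congener_tree()`) uses terminal branches of a few
hundredths of a substitution per codon for the three congeners — the
divergence range of a recently radiated genus (synonymous divergence
around 0.05–0.1) — plus a deeper outgroup. Calibration and power
experiments for the branch-site test instead use a four-taxon tree with
branch lengths of 0.1–0.4 substitutions per codon (total ≈ 1.15), the
regime in which published power analyses of branch-site LRTs are run and
in which the test is informative; measured power at the stated signal
(10% of sites at ω₂ = 5, 600 codons) is ≈ 95% there. At the shallow
study-like divergences the same signal is detected only ~20% of the time,
because a foreground branch of 0.03–0.04 substitutions per codon simply
carries too few changes — a caveat that applies equally to real scans of
recently diverged congeners. Type-I calibration and FDR-level control
hold on both trees. Problem sizes in the test suite (gene counts of tens
to hundreds, genes of 200–600 codons, 10,000-gene count matrices) are
chosen so each experiment carries enough Monte-Carlo resolution for the
property being checked while the whole suite stays desk-scale.

Numerical settings: optimizer relative tolerance $10^{-9}$–$10^{-10}$ in
log-likelihood, bounded parameters on log/logit scales, deterministic
multistart grids everywhere (fits are exactly reproducible), LRT statistics
clamped at zero, all-zero contingency tables reported as p = 1 with a
flag, and exact-test tie comparisons made with a $1 + 10^{-10}$ relative
guard so floating-point noise cannot drop an outcome from the tail sum.

## Known limitations

* Pairwise ML uses F3x4 or uniform frequencies only; no F61.
* Multi-species codon alignments are built by aligning to a reference
  protein pairwise; a true progressive multiple aligner may differ near
  gappy regions.
* The branch-site scan fixes branch lengths at the input tree's values;
  genes with strongly atypical rates are fit slightly conservatively.
* No Bayes empirical Bayes identification of selected sites — the scan
  reports gene-level evidence only.
* The no-replicate exact test cannot see fold changes below the
  dispersion floor discussed above; this is inherent to the design, not
  fixable by deeper sequencing.
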