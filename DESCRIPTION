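Package: congenerEvol
Title: Comparative Molecular Evolution and Expression Analysis for
    Invasive and Native Congeners
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of coding-sequence evolution and gene
    expression between closely related plant congeners, built around the
    question of what distinguishes an invasive species from its
    non-invasive relatives. Provides reciprocal-best-hit orthology and
    protein-guided codon alignment, Nei-Gojobori (1986) counting and
    Goldman-Yang codon-model maximum-likelihood estimation of Ka/Ks,
    per-category accelerated-evolution tests (pooled-count Fisher,
    binomial sign, and Wilcoxon signed-rank), free-ratio per-branch rates
    with lineage medians, branch-site positive-selection scans with
    likelihood ratio tests and FDR control, a fixed-dispersion
    negative-binomial exact test for two-sample differential expression
    without replicates, Fisher-exact category enrichment, and a seeded
    codon-evolution simulator with planted truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
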