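Package: targetsig
Title: Consensus Expression Signatures and Druggable Target Prioritization
    in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting a consensus differential-expression
    signature for a small target tumor cohort compared against many reference
    tissue groups, and for prioritizing druggable overexpressed genes by
    within-cohort percentile scoring. Implements empirical-Bayes moderated
    t-statistics with a trigamma moment-matched variance prior, pooled
    Benjamini-Hochberg false discovery rates across all pairwise comparisons,
    a direction-consistent fold/FDR consensus signature rule, percentile-based
    drug-target ranking, Spearman-distance complete-linkage sample clustering
    with Newick export, and hypergeometric gene-set over-representation.
    Includes a seeded synthetic-cohort generator with planted effects and
    ground truth for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
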