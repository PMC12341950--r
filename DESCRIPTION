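Package: plastiqtl
Title: Mapping cis- and trans-eQTL Underlying Gene Expression Plasticity in
    Biparental RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for expression QTL (eQTL) analysis of
    recombinant inbred line (RIL) populations measured under two environmental
    treatments. Partitions per-transcript expression variance into replicate,
    genotype, treatment and genotype-by-treatment components (type III ANOVA)
    with k-means clustering of variance profiles; builds per-genotype
    expression phenotypes for each treatment and a ratio-based plasticity
    phenotype (delta); runs single-QTL Haley-Knott regression genome scans
    with LOD peak calling; classifies eQTL as cis or trans from interpolated
    gene positions; merges eQTL across expression phenotypes and estimates
    effect sizes (R squared); detects trans-eQTL hotspots with sliding-window
    counts against a permutation-derived significance threshold; and annotates
    paralog and hotspot membership. Includes a synthetic generator of selfed
    RIL genotypes (Haldane-Waddington recombination) and treatment-responsive
    transcriptomes with planted eQTL architectures, so every stage is testable
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
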