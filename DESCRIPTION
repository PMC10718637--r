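Package: PresbyScan
Title: Audiometric Phenotype Classification and Rare-Variant Association
    in Adult-Onset Hearing Loss
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cohort studies of adult-onset (age-related) hearing
    loss. Decomposes pure-tone audiograms into metabolic and sensory
    presbyacusis components and classifies participants by sequential
    rules (Older-Normal, Metabolic, Sensory, Unclassified, Unselected);
    merges per-caller exome genotype calls into consensus genotypes and
    applies quality, Hardy-Weinberg excess-heterozygosity, cohort
    allele-frequency, mitochondrial and impact/MAF filters; detects
    per-gene variant-load outliers between phenotype groups by regression
    with an interquartile residual rule and tests outlier lists for gene-set
    enrichment; and scans individual variants for carrier threshold shifts
    with a sex-preserving permutation null and Benjamini-Hochberg
    correction. A synthetic-cohort generator with machine-readable truth
    tables exercises every stage without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    pracma,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
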