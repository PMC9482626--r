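Package: pedprio
Title: Pedigree-Based Rare-Variant Prioritization for Dominant Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate causal variants in small disease pedigrees
    sequenced by whole-genome sequencing. From an annotated multi-sample VCF,
    a PLINK-style pedigree file and a BED file of repeat-masked intervals, a
    filtering cascade applies site-quality, population-rarity,
    functional-class, in-silico deleteriousness-consensus and autosomal
    dominant co-segregation rules, annotates survivors with a computable
    subset of ACMG/AMP evidence criteria, and emits a candidate-variant
    report with a per-stage audit ledger. A method-of-moments pairwise
    identity-by-descent estimator (PLINK-style PI_HAT) supports pedigree
    quality control, and a gene-dropping cohort simulator with a planted
    fully penetrant dominant variant makes every stage testable without
    access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
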