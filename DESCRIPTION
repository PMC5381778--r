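Package: hbbcohort
Title: Consequence Annotation, Pathogenicity Consensus and Carrier Burden
    for Beta-Globin Cohort Variants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying coding variation in the beta-globin gene
    (HBB) across a multi-population diploid cohort.  Provides an exact
    minus-strand-aware gene model with codon and splice-window arithmetic,
    a variant consequence annotator (synonymous, missense, stop-gain,
    frameshift, splice donor/acceptor/region) validated against a
    whole-protein-diff oracle, an evidence-aggregation rule that combines
    clinical-database and in-silico-predictor labels into a per-variant
    pathogenicity verdict, per-population allele-frequency and
    carrier-burden summaries, and Hardy-Weinberg projections of
    next-generation hemoglobinopathy burden.  A seeded synthetic-data
    generator emits every pipeline input (FASTA, GFF3, multi-sample VCF,
    population map, evidence tables), including an exact reconstruction of
    a published 2,504-sample five-super-population study cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
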