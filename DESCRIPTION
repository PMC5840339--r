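Package: triohet
Title: Genomic Fidelity and Intra-Tumor Heterogeneity Analysis of
    Normal-Tumor-Culture Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for matched Normal / primary Tumor /
    patient-derived Culture ("trio") whole-exome variant calls. Applies
    depth, base-quality and strand acceptance rules to per-sample SNV
    calls, quantifies how faithfully a derived culture preserves the
    tumor's genetic identity (Jaccard similarity, shared-SNV
    percentages, cancer-gene-panel Venn overlaps, presence/absence PCA)
    and its intra-tumor heterogeneity (MATH, the mutant-allele tumor
    heterogeneity statistic 100 * MAD / median of tumor-specific
    variant allele fractions). Includes a synthetic trio-cohort
    simulator with known subclonal structure, tumor purity, culture
    normal-cell contamination and per-strand binomial read sampling,
    emitting the same VCF dialect the pipeline consumes plus a
    ground-truth sidecar.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'triohet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'heterogeneity.R'
    'io_filter.R'
    'pipeline.R'
    'plots.R'
    'relatedness.R'
    'setcomp.R'
    'simulate.R'
    'sitekeys.R'
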