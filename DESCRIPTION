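Package: hybridqtl
Title: Pooled-Segregant QTL Mapping for Inter-Species Hybrid Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bulk-segregant quantitative trait locus (QTL) mapping for
    multigenerational inter-species Saccharomyces hybrids. Covers colony-size
    phenotype quality control and two-tailed pool selection, derivation of
    founder-diagnostic SNP markers per sub-genome from haploid founder VCFs,
    pooled allele counting, a hidden-Markov-model contrast scan producing
    log10 likelihood-ratio (LOD) tracks comparing tied versus independent
    pool allele frequencies, QTL interval calling with 1-LOD support
    intervals and gene annotation, pleiotropy and cross-sub-genome shared-QTL
    analysis, and logistic growth-curve fitting for reciprocal-hemizygosity
    validation. Includes a synthetic F12-hybrid cross simulator emitting the
    same file formats the analysis consumes, so the full pipeline is
    exercisable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
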