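Package: homoeoScan
Title: Karyotype Aberration and Homoeologous Exchange Detection in
    Allotetraploids from Resequencing Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects chromosomal aberrations (aneuploidy, segmental
    deletion and duplication) and homoeologous exchanges in allotetraploid
    genomes from whole-genome resequencing observables. Combines a
    reduction-of-homoeologous-heterozygosity (ROH_H) chi-square scan over
    sliding windows of homoeologous variant sites with per-homoeolog
    depth-of-coverage (DOC) ratios over genomic windows of fixed
    non-repetitive content, fits integer homoeolog copy states with
    optional somatic-mosaic mixture fractions, and segments and classifies
    events with zygosity. Also provides deterministic depth-ratio genotype
    calling, windowed nucleotide diversity and introgression-block
    flagging across a resequencing panel, and a seeded synthetic
    allotetraploid data generator with ground-truth bookkeeping for
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
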