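Package: zcomp
Title: Assessing Z-Chromosome Dosage Compensation from RNA-Seq Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing chromosome-wide dosage compensation of the
    Z chromosome in female-heterogametic (ZW) species from bulk RNA-seq
    read counts. Computes RPKM with within-group quantile normalization,
    classifies male- and female-biased genes by expression fold-change
    (optionally gated on replicate-aware significance), derives the
    Z-to-autosome and male-to-female expression ratio panel with Wilcoxon
    rank tests before and after excluding sex-biased genes, and tests
    enrichment of sex-biased genes on the Z with a two-sided Fisher's exact
    test. Includes reciprocal-best-hit orthology transfer of chromosome
    assignments across species, old/new Z partitioning against an outgroup,
    faster-Z expression divergence (Euclidean distances of orthologous
    expression profiles) and NG86 Ka/Ks estimation from codon-aware
    alignments, and a seeded negative-binomial simulator that plants known
    dosage regimes and sex-biased genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    seqinr,
    withr,
    optparse
biocViews: Transcriptomics, GeneExpression, Normalization, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
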