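Package: mrmquant
Title: Targeted Proteomics Assay Design and Absolute Quantification by
    Scheduled Multiple Reaction Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative concatamer (QconCAT) based absolute
    protein quantification on triple-quadrupole instruments. Covers in
    silico proteolytic digestion and peptide mass arithmetic, proteotypic
    peptide selection from a FASTA proteome, assembly of artificial
    concatamer internal standards whose digestion releases every peptide
    intact, construction of scheduled multiple reaction monitoring (MRM)
    transition lists with declustering potential, collision energy and
    collision cell exit potential computed from linear functions of the
    precursor and fragment m/z, simulation of scheduled-MRM chromatograms
    with known ground truth, ratio-dot-product-gated light/heavy peak
    quantification in fmol per microgram, and downstream differential
    abundance statistics (fold change, t tests, volcano selection, one-way
    ANOVA with Sidak adjustment, PCA, clustered heat-map matrices) for
    three-group study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
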