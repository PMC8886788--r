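Package: PanNENmethyl
Title: Methylation-Based Classification and Cell-of-Origin Analysis of
    Pancreatic Neuroendocrine Neoplasms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for DNA methylation array analysis of pancreatic
    neuroendocrine neoplasms: consensus clustering of the most variable
    CpG probes, differential methylation on M-values with empirical-Bayes
    variance moderation, reference-atlas cell-type deconvolution by
    non-negative least squares, phylo-epigenetic neighbor-joining trees,
    and copy-number inference from methylated/unmethylated array
    intensities with circular binary segmentation. Includes a seeded
    synthetic-cohort generator that plants cell-type mixtures, group
    differentially methylated probes and copy-number segments with known
    ground truth, so that every stage of the analysis has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    ape,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pracma,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
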