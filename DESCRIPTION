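Package: abl1kd
Title: BCR::ABL1 Kinase-Domain Mutation Assay Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating an amplicon deep-sequencing
    assay for BCR::ABL1 kinase-domain (KD) resistance mutations in chronic
    myeloid leukemia. Provides a KD reference and 12-amplicon panel model, a
    seeded FASTQ read simulator with variant spike-ins, dilution series,
    replicate libraries and multi-sample cohorts, a transparent pileup-based
    low-VAF variant caller with QC gates and a 2 percent limit of detection,
    annotation of calls against a curated hotspot catalogue of mutations with
    poor sensitivity to tyrosine kinase inhibitors, and the validation
    statistics used for diagnostic assays (2x2 concordance metrics,
    dilution-series LOD analysis, replicate reproducibility, and cohort
    mutation-spectrum summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    VariantAnnotation,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
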