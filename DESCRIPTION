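Package: cryptsplice
Title: Detection and Characterization of SF3B1-Mutant Cryptic 3' Splice Sites
    from Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A junction-count pipeline for studying cryptic 3' splice-site
    activation in SF3B1-mutant cohorts. Reads splice-junction tables (STAR
    SJ.out.tab or a simple TSV dialect), calls alternative 3'/5' splice-site
    and exon-skipping events against a GTF annotation, quantifies percent
    spliced in (PSI) per event and sample, and tests for differential
    splicing between genotype groups with a log(PSI + x) transform,
    variability filter, mean imputation, standardization and two-sided
    t-test. Significant cryptic acceptors are characterized by their
    distance to the canonical site, polypyrimidine-tract and
    branchpoint-window composition, sequence-logo information content and a
    nonsense-mediated-decay flag; gene-level overlap between two cohorts is
    computed through an ortholog map, and a targeted amplicon module
    quantifies canonical versus misspliced isoform fractions. A bundled
    cohort simulator with a machine-readable truth table supports
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
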