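Package: cytoqc
Title: Quality Control, Contamination Estimation and Concordance Analytics
    for Targeted Panel Sequencing of Cytology Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quality-control computations used when profiling
    scant cytology specimens (cell blocks and supernatant cell-free DNA) with
    large hybridization-capture tumor panels sequenced against a matched
    normal. Estimates non-patient DNA contamination from panel SNP sites at
    which the patient is homozygous (method-of-moments and maximum-likelihood
    estimators with a 2% clinical cutoff), checks tumor-normal identity by
    genotype concordance to detect sample swaps, applies the multi-gate sample
    triage procedure (tumor content, era-dependent DNA input, coverage, base
    quality, contamination with a VAF-filter rescue for high-purity samples),
    computes panel tumor mutational burden and actionability summaries, and
    quantifies mutation concordance between matched cytology and surgical
    samples. A synthetic-cohort simulator with known ground truth
    (Hardy-Weinberg genotypes, two-person read mixtures, purity-scaled somatic
    VAFs, manifest-level cohorts) supports parameter-recovery testing, and a
    packaged fixture of published cohort counts supports reproduction of the
    corresponding headline rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
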