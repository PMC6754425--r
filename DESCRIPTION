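Package: cnipipe
Title: Copy Number Instability Scoring of Plasma Cell-Free DNA from
    Low-Coverage Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying chromosomal instability
    in circulating tumor DNA from shallow whole-genome sequencing. Read
    counts in fixed-width autosomal bins are corrected for GC bias,
    normalized against a healthy-plasma reference to relative copy number,
    segmented by a from-scratch circular binary segmentation (CBS)
    implementation, and summarized into a copy number instability (CNI)
    score: the sum of per-bin z values (z = sqrt(|log2(x/2)|)) over the
    bins ranked between the 95th and 99th percentile of z. Samples are
    classified as chromosomally instable (CIN) or stable (CNS) against a
    healthy-cohort cutoff (mean + SD), and longitudinal series are
    summarized for therapy-response monitoring. A synthetic-data generator
    emulates healthy cfDNA cohorts and tumor-patient timelines with
    GC-dependent bias, negative-binomial noise, segmental copy number
    alterations and tumor-fraction mixing, so the whole pipeline is
    testable without sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
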