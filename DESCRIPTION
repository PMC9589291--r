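Package: tempcre
Title: Temporal Discovery of Putative Cis-Regulatory Elements from
    Time-Course Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering putative cis-regulatory
    elements (pCREs) that drive temporal transcriptional responses, built
    around stress time-course RNA-seq contrasts. Genes are labelled
    up-/down-/non-responsive per time point from a differential-expression
    table, canonical k-mers (k = 5-8) enriched among responsive genes in
    five disjoint training bins become binary features, random-forest
    models are tuned by grid search under stratified cross-validation with
    in-fold class balancing (SMOTE or down-sampling), minimal pCRE sets
    are selected from a Michaelis-Menten fit to the F1-versus-feature-count
    ramp, and pCREs are categorised across time points, matched to known
    transcription-factor binding motifs by position-weight-matrix Pearson
    correlation with family-background significance thresholds, clustered
    by UPGMA on 1-PCC distance, and assessed by Fisher/Benjamini-Hochberg
    enrichment of GO terms, expression profiles, and pCRE presence. A
    synthetic-data generator plants motif instances into simulated gene
    regions with known ground truth so the whole pipeline is testable
    without external genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
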