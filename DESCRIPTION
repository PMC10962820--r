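Package: deltaprot
Title: Paired CSF Proteome Treatment-Effect Analysis with PRM Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired (pre/post-treatment) cerebrospinal
    fluid proteomics. Implements label-free discovery statistics (per-patient
    log2 fold changes, median fold change, percent concordance, paired t-tests
    with Benjamini-Hochberg correction, immunoglobulin keyword handling and a
    z-score fold-change cutoff), five-category comparison against a
    disease-vs-control reference list, hypergeometric gene-ontology
    over-representation, and parallel reaction monitoring (PRM) verification
    via weighted reverse calibration curves with automated linear-range and
    limit-of-quantification filtering. Ships a synthetic-cohort generator with
    known ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
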