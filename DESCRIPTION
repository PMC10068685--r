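Package: psmaquant
Title: Quantitative PSMA PET Tumor Burden Scoring and Treatment Response
    Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reference-normalized PSMA PET lesion quantification and
    treatment-response analysis for castration-sensitive prostate cancer
    imaging studies. Computes liver and blood-pool reference uptake from
    organ segmentations, detects and segments tracer-avid hot spots with
    an adaptive peak-relative threshold, scores lesions as volume times
    SUVmean normalized by reference SUVmean, aggregates scores by anatomic
    compartment (prostate/bed, nodal, osseous) and in composite, derives
    baseline-to-follow-up percent-change response tables with explicit
    missingness and new-disease handling, and correlates imaging response
    with PSA response (Pearson, two-tailed t significance, pairwise
    deletion). Ships a synthetic whole-body phantom and cohort simulator
    for end-to-end validation, plus transcribed per-patient response
    tables from a 30-patient cohort.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
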