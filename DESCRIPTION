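Package: petctdetect
Title: Lesion Detection and FROC Evaluation for FDG-PET/CT with Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated lung-cancer assessment on co-registered
    FDG-PET/CT volumes: intensity normalization and lung-based z-axis cropping,
    rule-based five-region anatomical segmentation (lung, mediastinum, bone,
    abdomen, other) with T/N/M attribution of detected lesions, patch-wise
    application of a pluggable lesion detector with prediction consolidation,
    and a complete free-response ROC (FROC) evaluation protocol with exact
    binomial confidence intervals, false-positive-per-case accounting and
    false-positive cause attribution. A seeded synthetic torso phantom
    generator provides paired CT/PET volumes with known anatomy and planted
    lesions so that the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
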