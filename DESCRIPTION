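Package: updrsalert
Title: Rough-Set Rule-Based Assessment of Motor-State Deterioration in
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying changes between pairs of UPDRS (Unified
    Parkinson's Disease Rating Scale) motor examinations into stable, warning
    and alarm states. Builds expert-labeled decision tables of per-item score
    changes, implements the rough-set machinery needed to handle conflicting
    expert labels (indiscernibility partitions, lower and upper approximations,
    quality of classification, discernibility matrices, reducts), induces
    human-readable interval-condition decision rules by sequential covering
    over cut-discretized deltas, and provides a variable-precision generalized
    variant that trades training-set coverage for out-of-sample accuracy.
    Includes a rule-based classifier with conflict resolution biased towards
    clinical safety, confusion-matrix evaluation under three collapsed-class
    efficiency cases, a nearest-neighbour sanity baseline, and a synthetic
    patient/expert simulator so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
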