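Package: bidsmapr
Title: Propose-and-Revise Mapping of Neuroimaging Conversion Outputs to BIDS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Headless curation engine that maps unorganized dcm2niix-style
    neuroimaging outputs (NIfTI images plus JSON sidecars) onto a compliant
    Brain Imaging Data Structure (BIDS) dataset. Infers subject and session
    labels from patient metadata and acquisition timestamps, groups scans into
    series by a four-field metadata key with a floating-point tolerance,
    classifies datatype and suffix through a three-stage heuristic chain,
    derives entity labels and run numbers, converts task-timing files to
    events.tsv and links them to their BOLD runs, validates the proposed
    mapping with an error/warning rule engine, assembles the BIDS tree, and
    supports reusable session templates. Includes a deterministic synthetic
    session generator so every stage is testable without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    RNifti,
    stringr,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
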