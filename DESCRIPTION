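Package: ehrwindows
Title: Documentation Frequency and Language Use Around Hospitalised Suicide Attempts in Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing electronic health record (EHR) free-text
    documentation in time windows proximal versus distal to a hospitalised
    suicide attempt. Consolidates Hospital Episode Statistics style
    consultant episodes into admission spells and flags suicide-related
    admissions by ICD-10 code; computes per-patient documentation-rate
    statistics (MonitoringLevel_W) and event-aligned coverage trajectories;
    selects proximal and distal document corpora under the window rules;
    prepares text through a deterministic POS-tagging and lemmatisation
    stage; scores words and word categories by document-level odds ratios
    with exact p-values; measures inter-annotator agreement (Cohen's kappa,
    per-category precision/recall/F1); and fits two-class multinomial Naive
    Bayes models over uni/bi/tri-gram features. A seeded synthetic-EHR
    generator with known ground truth (planted documentation ramps, word
    enrichments and categories) makes every stage testable without access
    to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
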