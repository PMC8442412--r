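Package: kickcut
Title: Contrasting-Groups Cut-Score Estimation for Electronic Kick-Impact Scoring
Version: 0.1.0
Authors@R: person("KickCut", "Maintainers", email = "maintainers@kickcut.dev", role = c("aut", "cre"))
Description: Implements the reference-group (contrasting-groups) standard-setting
    procedure used to evaluate kick-impact scoring thresholds in electronic
    taekwondo body protectors (PSS). Fits per-group normal impact distributions,
    solves for the intersection of the two densities to obtain a continuous
    cutoff, validates candidate integer scoring levels by classification
    accuracy with a sensitivity tie-break, and compares the selected levels
    against the federation-certified threshold table. Includes a seeded,
    stratified truncated-normal simulator that emulates the match composition
    and per-group impact statistics of elite competition data, so the whole
    pipeline is testable without access to raw match records.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
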