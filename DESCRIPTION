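Package: markerdig
Title: Internal-Marker Estimation of Fecal Output and Digestibility in
    Cattle Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the marker-ratio technique in ruminant digestion
    trials. Computes marker concentrations in consumed forage from offered
    hay and orts, fecal marker recovery, and marker-based estimates of
    fecal output and apparent dry-matter digestibility, and validates them
    against total-collection reference values. Includes validated CSV
    import/export for trial records, assay QC arithmetic for
    acid-detergent lignin (ADL), alkaline-peroxide lignin (APL) and
    acid-detergent insoluble ash (ADIA), a seeded simulator of replicated
    Youden-square (incomplete Latin square) feeding trials with known
    ground truth, diet-by-marker summary tables with bootstrap inference
    on fecal recovery, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
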