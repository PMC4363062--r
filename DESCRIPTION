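Package: ankledose
Title: Organ and Effective Dose Analysis for Extremity CT and Radiography Phantom Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Converts point-dosimeter (MOSFET) readings taken in a layered
    anthropomorphic ankle phantom into organ equivalent doses and ICRP-103
    effective doses, with per-tissue contribution breakdowns and modality
    (MSCT vs CBCT vs plain radiography) comparisons. Implements the full
    measurement-uncertainty budget: type-A statistical uncertainty from
    repeated exposures, combined point-dose uncertainty in quadrature with
    systematic components, tissue-dose uncertainty including the
    fraction-irradiated uncertainty, and the expanded (k = 2) effective-dose
    uncertainty. Includes helpers to derive fractions irradiated (Du Bois
    body surface area, skin-area and marrow-mass compositions) and a seeded
    synthetic-study generator emulating the non-uniform dose field along the
    scan axis and dose-dependent reading noise, so the whole pipeline is
    testable without physical measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
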