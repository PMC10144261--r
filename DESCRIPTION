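Package: svatriage
Title: Sequence Variant Triage and Quantitation for Peptide-Map LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Post-processing toolkit for sequence variant analysis (SVA) of
    recombinant protein therapeutics by peptide-map LC-MS/MS. Provides
    in-silico protease digestion (trypsin, Asp-N, thermolysin; fully and
    semi-specific), monoisotopic substitution mass arithmetic with
    isobaric-conflict detection, rule-based false-positive annotation of
    peptide-spectrum matches, score-cutoff calibration sweeps, relative
    quantitation of variant peptides from extracted-ion-chromatogram areas,
    run-comparison reporting, and a seeded synthetic peptide-map and
    data-dependent-acquisition simulator that reproduces the injection-time
    gating bias affecting low-level quantitation on some Orbitrap platforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
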