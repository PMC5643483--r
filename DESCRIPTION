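Package: exometab
Title: Untargeted Exometabolome Annotation from Ultrahigh-Resolution
    Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for annotating bacterial exometabolomes measured
    by ultrahigh-resolution mass spectrometry (FT-ICR-MS). Reads peak lists,
    filters by signal-to-noise and mass window, recalibrates spectra, converts
    ions to neutral masses, assigns CHNOSP molecular formulas by constrained
    exhaustive enumeration with standard plausibility filters, subtracts
    sterile-control blanks, matches formulas against a genome-predicted
    metabolite database, classifies matches by pathway role and functional
    group, screens them against environmental dissolved organic matter formula
    sets, and provides batch-growth and carbon mass-balance diagnostics
    (growth-rate fitting, growth-stimulation tests, lysis detection from
    dissolved combined amino acid carbon). Seeded generators simulate every
    input with ground-truth manifests so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
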