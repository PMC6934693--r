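Package: revdrive
Title: Deterministic Modeling of Inducible and Reversible CRISPR Gene Drives
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic frequency-based population model of a CRISPR
    homing gene drive with no resistance alleles, together with three
    externally inducible reversal mechanisms: an inducible drive efficiency,
    an inducible carrier fitness, and an inducible self-cleaving drive whose
    activation excises the drive cassette. Provides single-generation update
    rules, multi-generation trajectory simulation with fixation detection,
    two-parameter phase-diagram sweeps, invasion-threshold bisection,
    closed-form invasion diagnostics, and an independent genotype-enumeration
    oracle (with a finite-population Wright-Fisher check) used to validate
    every recursion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
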