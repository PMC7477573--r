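Package: buometry
Title: Metrology and Logic Composition for Engineered Anti-Repressor Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing engineered allosteric transcription
    factors (repressors, anti-repressors, super-repressors) as biological
    unit operations and for composing them into genetic logic gates.
    Includes a plate-reader and flow-cytometry simulator with realistic
    replicate structure and controls, promoter/operator cassette builders
    for core, proximal, series and parallel architectures, statistical
    phenotype classification (Welch t-test, Cohen's d), performance-card
    metrology with traceability scores against a reference unit operation,
    an architecture-based truth-table composition model with ANOVA/Tukey
    gate evaluation, and library-design calculators (NNS site-saturation
    coverage, error-prone PCR mutation statistics, two-step FACS sort
    enrichment simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
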