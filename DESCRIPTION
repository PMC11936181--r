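Package: DockTriage
Title: Multi-Target Molecular-Docking Triage for Anti-Osteoarthritis
    Compound Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for triaging compound libraries screened by multi-target
    molecular docking against the MAPK (ERK2, JNK2, p38) and NF-kB (p65,
    IkBa) pathway proteins. Reduces per-pose docking energies to
    representative binding energies, computes weighted multi-target /
    anti-target scores and ascending rankings, applies per-target energy
    thresholds with an anti-target ceiling, evaluates Lipinski rule-of-5
    drug-likeness, runs the candidate-selection procedure (top-N,
    anti-inflammatory filter, known-compound exclusion) with an audit
    trail, and reproduces the downstream in-vitro assay arithmetic (CCK-8
    viability with the ISO 10993-5 70 percent rule, nitrite quantification
    from a linear standard curve, two-tailed unpaired t-tests with
    significance stars). A seeded synthetic-data module generates docking
    energy tables, pose-file trees and assay plates with planted effects
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
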