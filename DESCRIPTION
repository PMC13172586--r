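Package: stonescreen
Title: Physicochemical Profiling of Urinary Proteins and Correlation
    Screening Against Calcium Oxalate Crystal-Promoting Activities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking sequence-derived physicochemical
    properties of urinary proteins to calcium oxalate (CaOx) crystal-promoting
    activities measured on chromatographic protein fractions. Computes
    ProtParam-equivalent descriptors (average-mass molecular weight,
    theoretical isoelectric point, GRAVY hydropathicity, Guruprasad
    instability index, residue-class composition), scans PROSITE-syntax
    oxalate-binding motifs, counts calcium-binding sites from UniProt
    flat-text feature annotations, predicts four-state secondary-structure
    fractions with a window-averaged propensity method, converts raw crystal
    assay readouts (crystallization, growth, aggregation, crystal-cell
    adhesion) into promoting-activity percentages against a reference
    control, and screens abundance-weighted properties against
    abundance-weighted activities with Spearman rank correlation,
    Benjamini-Hochberg adjustment and an |rs| > 0.8 significance rule.
    Includes a seeded synthetic-data generator with planted property-activity
    links for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
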