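Package: hepaflux
Title: Sex-Biased Metabolic Subsystems and Context-Specific Flux Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing male and female tissue metabolism with
    genome-scale metabolic models (GEMs).  Scores metabolic subsystems by
    differential expression projected through gene-protein-reaction (GPR)
    rules with an empirical permutation null (TIDEs-style), extracts
    transcript-guided context-specific models by weighted flux-sum
    minimization and pruning with constrained hit-and-run flux sampling
    (RIPTiDe-style), compares cohorts of context models by reaction
    presence and uniqueness, contrasts per-reaction flux distributions,
    and analyses sex-stratified adverse-event report proportions.  A
    synthetic-data module generates a small liver-like GEM, expression
    cohorts with planted sex effects, and quarterly adverse-event tables
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
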