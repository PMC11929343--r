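Package: mrmediate
Title: Two-Sample Mendelian Randomization and Cox Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Triangulated analysis of a modifiable exposure and a disease
    outcome: two-sample Mendelian randomization with a full sensitivity
    suite (inverse-variance weighted, weighted median, MR-Egger, MR-PRESSO),
    instrument selection with LD clumping and effect-allele harmonization,
    two-step Mendelian randomization mediation with delta-method confidence
    intervals, and an observational arm with Cox proportional-hazards
    models, Schoenfeld diagnostics, linear mediator screening and
    difference-method mediation. Includes seeded generators for synthetic
    GWAS summary statistics (from single-SNP regressions on simulated
    genotypes) and synthetic survival cohorts, so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
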