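Package: chtrace
Title: Clonal Haematopoiesis Trajectories and Clone Growth-Rate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the dynamics of clonal haematopoiesis from
    ultrasensitive targeted sequencing of blood DNA. Implements replicate-aware
    calling of clonal haematopoiesis driver mutations (CHDMs) from paired
    technical-replicate read counts, assembly and classification of per-individual
    variant-allele-frequency (VAF) trajectories over repeated sampling (growing,
    static, shrinking, events, late-appearing clones), estimation of per-individual
    clone growth rates with a random-intercept/random-slope mixed model of log VAF
    on age, and rank-correlation of growth rates with metabolic covariates under
    Bonferroni control. A synthetic-cohort generator reproduces the longitudinal
    data structure of an obesity cohort (dual-replicate binomial read noise,
    staggered follow-up with missingness, a clinical panel whose HDL-cholesterol is
    copula-linked to true clone growth) so the full pipeline is testable without
    access to individual-level human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
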