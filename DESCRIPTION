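Package: ervkit
Title: Characterization, Dating and Mutation Signatures of Endogenous
    Retrovirus Proviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for paleovirological analysis of full-length endogenous
    retrovirus (ERV) proviruses such as the simian endogenous retrovirus
    (SERV) of Old World monkeys. Validates provirus loci (terminal LTR
    detection, target-site duplications, primer-binding-site extraction and
    tRNA-primer classification, ORF interruption scanning), computes
    Kimura-2-parameter distances under pairwise- or complete-deletion gap
    policies, dates germ-line integrations from LTR divergence via T = K/2r,
    censuses CpG methylation-associated deamination (TpG/CpA), scans for
    APOBEC3-type context-dependent G-to-A hypermutation with exact-test
    enrichment, and tests neutrality with Tajima's D. A truth-tagged
    endogenization simulator generates provirus cohorts with known ages,
    mutation logs, and editing episodes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
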