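Package: eodase
Title: Allele-Specific Expression and Expression Patterns During
    Electric-Organ Ontogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for gene expression and allele-specific
    expression (ASE) during the ontogeny of the mormyrid electric organ.
    Discovers fixed biallelic differences between two parental species
    cohorts from a VCF, quantifies parental-allele proportions in F1
    hybrids from allelic depths, classifies genes as balanced or
    parent-dominant, detects ontogenetic allelic shifts between juvenile
    and adult stages, and tests stage differences on arcsine-transformed
    proportions. Companion expression stages provide low-count filtering,
    median-of-ratios normalization, covariance PCA, a negative-binomial
    likelihood-ratio test of association between expression and electric
    organ discharge (EOD) duration, monotone expression-pattern
    clustering, pairwise adult-versus-juvenile differential expression,
    Venn set construction, candidate triage across evidence lists, and
    Fisher's exact enrichment. A synthetic-data generator with known
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    graphics,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
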