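Package: epitrio
Title: Case-Only Epistasis Screening, Trio-Based Association and Modifier
    QTL Meta-Analysis for Family Genetic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reverse-pathway genetic analysis in case-parent trio
    cohorts: an allelic case-only gene-gene interaction (epistasis) screen
    restricted to a pathway SNP set with same-chromosome exclusion and
    pseudo-control / matched-sex parent-control comparisons; the
    transmission disequilibrium test with permutation-based, length-matched
    gene-set enrichment of association; a trio correlation test that
    validates candidate interacting pairs using expected offspring
    genotypes; and modifier-QTL mapping of quantitative traits with
    cross-group random-effects (Han-Eskin RE2) meta-analysis and Cochran's
    Q heterogeneity. Includes a synthetic trio-cohort and quantitative-trait
    generator (Hardy-Weinberg founders, Mendelian transmission, logistic
    ascertainment of affected offspring) so every stage is testable without
    external data, plus PLINK text .ped/.map readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
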