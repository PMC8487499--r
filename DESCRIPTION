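Package: zwscan
Title: Sex-Linked Marker Discovery and Hemizygous Copy-Number Detection
    from Genotyping-by-Sequencing Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering sex-associated markers and
    characterising sex chromosome systems in dioecious species from
    genotyping-by-sequencing (GBS) allele-depth data. Implements
    maximum-likelihood genotype calling from per-allele read counts,
    genome-wide association of sex by Freeman-Halton exact contingency
    tests with Bonferroni control and by a single-marker mixed linear
    model with population structure and kinship (per-marker REML),
    classification of segregation patterns diagnostic of ZW versus XY
    heterogamety, detection of collapsed-paralog markers and hemizygous
    sex-specific copy-number variation from allele-specific read depths,
    and anchoring of assembly scaffolds to chromosomes through linkage-map
    markers. A configurable simulator of ZW dioecious populations with
    GBS-like negative-binomial read depths makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
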