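Package: pedfunnel
Title: Family-Based Variant Prioritization, Parametric Linkage and Brain
    Expression Correlation
Version: 0.1.0
Authors@R:
    person("pedfunnel", "maintainers", email = "pedfunnel@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-genome variant prioritization in families
    segregating an autosomal-dominant trait: a staged filtering funnel
    (genotype quality, shared identity-by-state haplotype regions, dominant
    segregation, population rarity, functional class, gene-list membership,
    pathogenicity-score voting, candidate-gene network prioritization) with
    per-stage audit reports; exact single-locus parametric pedigree
    likelihoods, LOD scores over the recombination fraction and
    simulated-marker maximal-LOD power analysis; Mendelian-error and
    kinship checks; probe-level expression quality control, gene-level
    correlation and Fisher-z comparison of correlations; and fully seeded
    synthetic-data generators (gene dropping, annotation tables,
    correlated expression matrices) so that every stage is testable
    without access to private genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    MASS,
    optparse,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
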