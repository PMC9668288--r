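Package: rvburden
Title: Rare-Variant Gene-Level Collapsing Association Testing
Version: 0.1.0
Authors@R:
    person("rvburden", "developers", email = "rvburden@example.org", role = c("aut", "cre"))
Description: Gene-level collapsing burden analysis for exome cohorts: per-genotype and
    per-site quality control, qualifying-variant model registries (dominant, recessive
    with hemizygous and putative compound-heterozygous coding, and a synonymous
    negative-control model), Fisher's exact and covariate-adjusted linear burden tests
    with sex-matched controls and rank-based inverse-normal transformation,
    variant-level exome-wide association tests, Cochran-Mantel-Haenszel stratified
    meta-analysis with heterogeneity and genomic-inflation diagnostics, and follow-up
    analyses (conditional joint regression, leave-variants-out collapsing, risk-haplotype
    effect modification, pairwise linkage disequilibrium). Includes a synthetic
    exome-cohort simulator with ancestry strata, X-linked recessive architectures and a
    gene-by-haplotype interaction, used for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
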