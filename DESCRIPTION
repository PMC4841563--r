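Package: mfrg
Title: Multivariate Functional Regression Tests of Gene-Gene Interaction
    for Multiple Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based tests of epistasis (gene-gene interaction) for one or
    more correlated quantitative traits.  Genotype profiles of a genomic
    region are treated as functions of genomic position, expanded in
    functional principal components, and the interaction between two regions
    is tested in a multivariate multiple regression with Wald and
    likelihood-ratio statistics that are asymptotically chi-square with
    K*J*L degrees of freedom.  Includes the standard comparator tests
    (single-trait functional regression, regression on ordinary principal
    components, permutation-adjusted pairwise SNP scans), a synthetic
    haplotype-pool simulator for type-I-error and power studies under
    two-locus penetrance models, and a scan driver for VCF input with
    covariate adjustment, Bonferroni control, QQ diagnostics and
    interaction-network output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
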