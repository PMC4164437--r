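Package: podscore
Title: Proportional-Odds Score Test for Genotype-on-Phenotype Association
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reverse-regression association testing for biallelic markers:
    the genotype (0/1/2 copies of an allele) is modelled as an ordinal
    response of one or more phenotypes through the proportional odds
    (cumulative logit) model. Provides a closed-form score test built from
    sample genotype proportions, the likelihood-ratio counterpart fitted by
    Newton-Raphson, analytic non-centrality and power calculations for
    case-control designs under Hardy-Weinberg equilibrium, seedable
    simulators for case-control and correlated multivariate-phenotype data,
    the Cochran-Armitage trend and Pearson chi-square reference tests, a
    genome-scan interface over VCF or tabular genotypes, and a study harness
    that regenerates the type-I-error and power experiments characterizing
    the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
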