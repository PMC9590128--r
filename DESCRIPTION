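Package: skatpipe
Title: Clinically Guided Gene-Based Rare-Variant Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A four-stage pipeline for gene-based association analysis of
    rare and common variants. Stage one screens variants with single-variant
    association tests (Fisher exact, chi-square, Cochran-Armitage trend,
    logistic, linear, log-rank and Cox regression) under additive, dominant
    or recessive genetic models. Stage two maps the retained variants to
    genes and runs hypergeometric over-representation analysis against
    user-supplied gene-set collections. Stage three computes per-variant
    collapsing weights from reference-population minor allele frequencies
    via a logistic weighting function, with the Beta-density scheme as an
    alternative. Stage four runs the sequence kernel association test
    (SKAT) per gene unit, with Davies characteristic-function inversion and
    the Liu moment-matching approximation for mixture-of-chi-square
    p-values. Includes native PLINK binary and VCF genotype readers, a
    synthetic-cohort generator, Manhattan/QQ/LD/gene-bar plots, and a
    single-config pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    ggplot2,
    rlang,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
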