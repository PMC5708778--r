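Package: ntr
Title: Non-Threshold Rare-Variant Region Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Region-based case-control association testing for rare and
    common variants without a minor-allele-frequency threshold. Variants are
    weighted by the reciprocal of their minor allele frequency and the
    magnitude of their log2 odds ratio, pairwise terms are down-weighted by
    Hedrick's multiallelic D-prime so that variants in strong linkage
    disequilibrium carry less redundant signal, and the resulting
    per-individual genetic scores are tested with a permutation rank-sum
    statistic minimised over three pair-weighting schemes. Includes a
    latent-Gaussian AR(1) genotype simulator for power and type-I-error
    studies, re-implementations of the CMC, WSS, SKAT and SKAT-O comparator
    tests, a Cochran-Armitage trend test wrapper, VCF/PLINK input with
    call-rate and Hardy-Weinberg quality control, and an experiment driver
    for scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
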