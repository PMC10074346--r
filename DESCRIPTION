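Package: rvburden
Title: Gene-Based Rare-Variant Collapsing Burden Tests with Firth Correction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide gene-based rare-variant collapsing
    burden association analysis in stratified case-control cohorts.
    Qualifying variants are selected per gene by consequence class, reference
    allele frequency and deleteriousness score, collapsed into genetic scores
    under co-dominant, heterozygous, recessive and dominant models (with
    hemizygous X handling), and tested with a likelihood-ratio test under
    maximum-likelihood or Firth-penalized logistic regression adjusted for
    sex, age and principal components. Includes sample-size weighted Z
    meta-analysis across ancestry and pipeline strata, an eigenvalue-based
    effective number of tests, candidate gene-set enrichment with a
    matched-gene resampling null, zygosity-differential odds-ratio tests,
    frequency-weighted common-plus-rare burden scores, Monte-Carlo power
    estimation, PCA-based stratification covariates, and a synthetic-cohort
    generator with planted risk genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
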