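Package: ldscreg
Title: LD Score Regression for Cross-Trait Heritability, Genetic
    Correlation and Functional Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of SNP-heritability and cross-trait genetic
    correlation from GWAS summary statistics by LD score regression, with
    block-jackknife standard errors, liability-scale conversion for
    case-control traits, locus-exclusion heritability attribution, local
    (region-level) genetic covariance scans, directional model comparison
    between trait pairs, and stratified regression for functional-annotation
    enrichment with random-effects meta-analysis across traits.  Includes a
    summary-statistic simulator with block-structured linkage disequilibrium
    and known truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    metafor,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
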