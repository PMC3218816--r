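Package: gxescan
Title: Combined Main-Effect and Genotype-by-Intervention Association Testing
    in Randomized Trial Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome scans that combine evidence of overall
    case-control association with evidence of genotype-by-randomized-
    intervention interaction, as used in nested case-control samples from
    partial factorial prevention trials such as the Women's Health
    Initiative. Implements per-SNP logistic score tests, case-only
    interaction score tests with a known-randomization-fraction offset,
    sandwich covariance assembly across overlapping trial components, the
    combined five-degree-of-freedom chi-square test, rank-based false
    discovery rate estimation, genotype-stratified intervention odds
    ratios with two-degree-of-freedom interaction likelihood ratio tests,
    ROC/AUC discrimination analysis with a matched-pair bootstrap, genotype
    summary statistics (minor allele frequency, linkage-disequilibrium r
    squared, adjacent-locus binning, stratification-adjustment principal
    components), and a synthetic partial-factorial trial cohort generator
    for validation without access to the original trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
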