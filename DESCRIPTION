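Package: mrinflame
Title: Two-Sample Mendelian Randomization for Serum Inflammatory Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization analyses of serum
    inflammatory biomarkers (IL-18, IL-1ra, IL-6, erythrocyte sedimentation
    rate) on Alzheimer's disease risk, and for summary-statistic MR more
    generally. Provides readers and validators for GWAS summary statistics
    and pairwise-LD tables, p-value/MAF instrument filtering, LD clumping,
    allele harmonization across exposure and outcome datasets (allele-order
    swaps, strand flips, palindromic-SNP frequency alignment, proxy SNP
    substitution), Wald-ratio, inverse-variance-weighted and MR-Egger causal
    estimators with odds-ratio-scale reporting, per-instrument variance
    explained and instrument-strength summaries, MR power and minimum sample
    size calculations for binary outcomes, and a synthetic summary-statistic
    generator with known ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
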