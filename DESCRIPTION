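Package: proteomr
Title: Proteome-by-Phenome Mendelian Randomization with Multi-Tissue pQTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for inferring protein effects on complex
    phenotypes from multi-tissue protein quantitative trait loci (pQTLs).
    Covers aptamer-proteomics quality control (detection-limit, calibrator
    coefficient-of-variation, scale-factor and interquartile-range filters
    with iterative sample-outlier removal), additive-model pQTL mapping with
    a principal-component-derived study-wide significance threshold,
    fixed-effect meta-analysis with heterogeneity flags, instrument selection
    (pleiotropy filter, LD clumping, F-statistic cutoff) under cis-only and
    cis+trans workflows, two-sample Mendelian randomization (Wald ratio and
    inverse-variance-weighted estimators with summary-statistic
    harmonization, FDR control and Steiger directionality filtering),
    approximate-Bayes-factor colocalization, cross-tissue concordance and
    replication statistics, and druggable-genome / drug-repurposing
    annotation. Includes a synthetic-data generator with known causal
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
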