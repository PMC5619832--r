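Package: pleioscan
Title: Genetic Risk Scores and Causal-Network Pleiotropy Scans for BMI and Smoking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds polygenic (genetic) risk scores for body mass index from
    GWAS summary statistics with p-value selection and greedy LD/distance
    pruning, and screens individual variants for pleiotropic effects on BMI
    and smoking phenotypes by scoring twelve directed acyclic graphs over
    {SNP, BMI, smoking} with a two-regression AIC and a minimum-AIC category
    rule. Includes maximum-likelihood Gaussian and Bernoulli regression
    utilities (log-likelihoods, Wald tests, partial correlations, adjusted
    group means, ordinal trend tests), a synthetic cohort generator that
    draws Hardy-Weinberg genotypes, covariates and trio phenotypes under any
    of the twelve causal structures, covariate-adjusted association analyses
    of the score against BMI categories and smoking behaviour, external
    summary-statistic validation with Bonferroni correction, and an
    end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
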