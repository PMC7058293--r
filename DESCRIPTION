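Package: hccnma
Title: Bayesian Network Meta-Analysis of First-Line Targeted Therapies in
    Advanced Hepatocellular Carcinoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrast-based Bayesian network meta-analysis (NMA) of
    randomized trials of first-line targeted drugs for advanced hepatocellular
    carcinoma, and for any evidence network of log hazard-ratio or log
    odds-ratio contrasts. Reconstructs log effects and standard errors from
    reported confidence intervals, log-rank p-values or tabulated
    Kaplan-Meier summaries; runs direct pairwise meta-analysis
    (inverse-variance fixed effect, DerSimonian-Laird random effects,
    Mantel-Haenszel odds-ratio pooling, Cochran's Q and I-squared); fits
    hierarchical Bayesian consistency and unrelated-mean-effects models by
    conjugate Gibbs sampling with deviance information criterion model
    comparison; assesses inconsistency by node-splitting; ranks treatments by
    rank probabilities and the surface under the cumulative ranking curve
    (SUCRA) with two-outcome clustered ranking; and exports
    comparison-adjusted funnel-plot data. Includes seeded simulators of
    evidence networks with known truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
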