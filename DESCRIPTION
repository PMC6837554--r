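Package: pmscreen
Title: Quantitative Plasma-Membrane Proteome Screening and Fluorescence
    Ratio Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-tier differential plasma-membrane (PM) proteome
    screen of the kind used to map alpha-arrestin adaptors to their endocytic
    cargo in yeast. Implements per-replicate protein fold-change estimation
    from peptide-level isobaric-label ratios, geometric-mean pooling across
    biological replicates, peptide-count-weighted Stouffer combination of
    per-replicate p-values with Bonferroni correction, and a screening
    classifier that first selects cycloheximide-affected PM proteins and then
    calls, per arrestin deletion strain, whether each protein is stabilized
    or depleted at the PM. Ships a seeded synthetic peptide-ratio generator
    with known ground truth for power and type-I calibration, machine-readable
    copies of the published screen tables, and a fluorescence module that
    measures per-cell internal-over-PM intensity ratios from concentric
    ellipse regions, summarizes conditions by median with bootstrap 95%
    confidence intervals, and compares conditions with Wilcoxon rank-sum
    tests under Holm adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
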