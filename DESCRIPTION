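Package: ipscore
Title: Individual-Level Pathway Scores from Single-Sample Correlation Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how strongly each pathway is perturbed in a single
    sample by measuring the change in edge-wise Pearson correlation when that
    sample is added to a reference panel of normal samples (the individual-level
    pathway score, iPS). Tumor samples are classified per pathway as
    perturbed-strong or perturbed-weak against the normal-sample iPS
    distribution, and prognosis-related pathways are screened with a
    Wilcoxon rank-sum test (Benjamini-Hochberg FDR) followed by Kaplan-Meier
    log-rank survival analysis. Includes a synthetic-cohort simulator with
    planted correlation perturbations and survival effects, TSV readers and
    writers for expression, pathway edge-list, and clinical tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
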