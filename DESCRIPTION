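Package: neurostates
Type: Package
Title: Neurogenomic States from Brain-Region qPCR Co-Expression in Dyadic Contest Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for candidate-gene qPCR studies of
    social-status effects on brain gene expression. Generates synthetic dyadic
    agonistic-contest studies (winners, losers, mirror-fighters and isolated
    controls across five brain nuclei), quantifies amplification curves into
    relative initial template concentrations with reference-gene normalization,
    screens outliers with the generalized extreme studentized deviate procedure,
    fits linear mixed models with subject and dyad random effects and planned
    treatment contrasts with Cohen's effect sizes, and compares per-condition
    gene co-expression matrices ("neurogenomic states") with quadratic
    assignment procedure (QAP) permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    lme4,
    lmerTest,
    emmeans,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    pheatmap
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
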