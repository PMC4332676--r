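Package: ebtrans
Title: Evidence-Based Translation of Model-Organism Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evidence-based translation (EBT) of two-class
    differential-expression results from a model organism (typically mouse)
    to a target human system. From a prior paired model/human experiment the
    package estimates a nonnegative per-gene pseudo variance that quantifies
    how poorly each gene's response translates; the pseudo variance then
    penalizes the t-statistics of a new model-organism experiment so that
    discordantly translating genes lose significance. Includes the
    unpenalized conventional-translation baseline, an exclusion baseline,
    direction-agreement and gene-set (Fisher exact) concordance
    evaluations, tabular ingestion with probe-set collapse and ortholog
    joining, a synthetic paired-study generator with known translation
    structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
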