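Package: reservoirtask
Title: Reservoir-Network Simulation of Task-State Learning in the
    Orbitofrontal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a fixed, sparse, random recurrent rate network (a
    reservoir, or state-encoding layer) that receives task events --
    including reward -- as inputs, and whose two-unit softmax readout is
    trained with a reward-modulated Hebbian rule.  Implements three
    behavioural paradigms (deterministic reversal learning, a two-stage
    Markov decision task, and a value-based economic choice task),
    manipulations of the model (reward-input lesion, decision-time
    inactivation, learning freeze), and the accompanying analysis battery:
    errors-to-criterion learning curves, selectivity classification and
    category grouping, population PCA, stay-probability factorial analysis
    and the task-structure index, hybrid model-based/model-free maximum
    likelihood fitting, lagged-state and factor logistic regressions,
    choice psychometrics, and the ten-variable value-selectivity taxonomy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tidyr,
    withr
Config/testthat/edition: 3
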