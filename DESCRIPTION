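Package: marfsga
Title: Multi-Agent Reinforcement-Learning Feature Selection with Guide Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for labelled tabular data (for example
    gene-expression biomarker panels) driven by multi-agent Q-learning. One
    epsilon-greedy "main" agent per feature decides whether to select that
    feature; a stateless random "guide" agent per feature provides the
    comparison baseline. The learning signal is the difference between the
    classification accuracy of the main-selected subset and the
    guide-selected subset, applied only to agents whose action disagrees
    with their guide counterpart. Includes a small feed-forward network
    reward environment, a synthetic benchmark generator with planted ground
    truth, the no-guide ablation, and self-contained mRMR, ReliefF and
    genetic-algorithm comparators, with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
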