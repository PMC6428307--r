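Package: mixedpc
Title: Constraint-Based Causal Discovery with Mixed Continuous, Nominal and
    Ordinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symmetric conditional-independence tests for mixed data types
    (continuous, binary, nominal, ordinal) built from nested likelihood-ratio
    and F tests on linear, binary/multinomial logistic and generalized ordered
    logit regression models, together with methods for combining the two
    directional p values (MM, minimum, maximum) or prioritizing a single
    direction (Fast). The tests plug into an order-independent PC (PC-stable)
    structure learner that returns a partially directed acyclic graph. Includes
    a synthetic mixed-data Bayesian-network generator, CPDAG conversion,
    skeleton/orientation precision-recall and structural-Hamming-distance
    metrics, and Monte-Carlo harnesses for test calibration and network
    recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
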