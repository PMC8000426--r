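Package: ibcolor
Title: Emergent Color-Naming Systems and Information Bottleneck Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the efficiency of color-naming systems on the
    Information Bottleneck (IB) complexity/accuracy plane. Two feed-forward
    neural agents (Speaker and Listener) play a color-discrimination game
    over a discrete channel, trained either with the Gumbel-Softmax
    relaxation or with REINFORCE. Emergent naming systems are extracted by
    sampling the converged Speaker, scored by mutual-information complexity
    and accuracy under a Gaussian meaning model over CIELAB color chips,
    and compared against the theoretical IB limit curve computed by
    reverse deterministic annealing, a fuzzy c-means clustering baseline
    played with Bayesian listeners, and (optionally) human World Color
    Survey naming data. Includes a synthetic palette and naming-system
    generator so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
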