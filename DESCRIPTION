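Package: smpassoc
Title: Semi-Markov Process Models of Free Association and Thought Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative modelling and likelihood-based inference for repeated
    free-association data under proactive and reactive thought control. The
    package implements a semi-Markov process in which candidate associations
    are sampled in proportion to their associative strength, take
    Gamma-distributed times to generate, and may be rejected if they repeat an
    earlier response. It provides the exact joint choice/response-time
    likelihood for four model variants via Laplace-transform inversion,
    per-participant maximum-likelihood fitting with BIC model comparison,
    estimation of covert association spaces from free-association norms and
    strength ratings, a synthetic-cohort generator with known ground truth,
    and the surrounding analysis pipeline (trial classification, exclusions,
    descriptive group contrasts, absolute-fit checks, and parameter and
    model recovery studies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
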