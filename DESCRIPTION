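Package: levywolf
Title: Levy-Flight Grey Wolf Optimization for Neural-Network Prognosis Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An enhanced Grey Wolf Optimizer (LGWO) combining an
    arctan-decayed weight factor, Levy-flight stagnation escapes via the
    Mantegna sampler, opposition-based learning, drift and contraction
    moves, and Harris-Hawks-style mutation under greedy acceptance;
    together with the canonical Grey Wolf Optimizer baseline, a suite of
    18 classical benchmark objectives, a single-hidden-layer sigmoid
    network whose weights are trained by LGWO and refined by
    backpropagation (LGWO-BP) for binary prognosis classification, a
    Pearson-correlation feature-ranking step, seeded synthetic data
    generators emulating omics-style tables with a binary outcome, and an
    evaluation harness (classification metrics, repeated-run statistics,
    Wilcoxon rank-sum and signed-rank tests, Cohen's d, Brier score,
    k-fold cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
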