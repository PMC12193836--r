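# levywolf

Levy-flight-enhanced Grey Wolf optimization (LGWO) and the LGWO-BP hybrid
classifier for binary prognosis modelling, with the canonical Grey Wolf
Optimizer baseline, an 18-function benchmark suite, and a full evaluation
harness.

## The problem and the method

Training a feedforward network by gradient descent alone is sensitive to
its random starting point: backpropagation converges to the nearest local
optimum of the error surface. For small clinical prognosis models — a
single-hidden-layer sigmoid network predicting a 0/1 outcome such as
disease progression from a handful of screened molecular features — a
population metaheuristic can instead search the whole weight space first,
and gradient descent can polish the result.

The Grey Wolf Optimizer steers a population ("pack") of candidate weight
vectors by its three best members: each agent moves to the mean of three
leader-anchored points `X_l - A ∘ |C ∘ X_l - x|` with `A ~ U(-a, a)`,
`C ~ U(0, 2)` per coordinate and `a(t) = 2(1 - t/T)` shrinking over the
run. LGWO adds five mechanisms:

* an arctan-decayed weight factor
  `O(t) = ((T-2)/T) · (w_s - (w_s - w_e) · (2/π) arctan(a + b t))²`,
* Levy-flight repositioning of non-leader wolves,
  `S = 0.01 · ℓ ∘ (x - x_α)` with heavy-tailed Mantegna draws `ℓ`,
* opposition-based learning and a best/worst Levy candidate for the
  incumbent best,
* per-wolf drift `x + L(x_best - x)` and contraction `O·x` candidates,
* Harris-Hawks-style mutation with probability `pp` per wolf,

all candidates accepted greedily. The hybrid **LGWO-BP** classifier
(`lgwo_nnet()`) searches the flat weight vector of the network in
`[-1, 1]` against the training MSE (5 agents, 30 iterations), then
refines by full-batch backpropagation.

## Worked example

```r
library(levywolf)

# 1. benchmark the optimizer: Ackley, 30-d, full protocol
fb <- get_benchmark("f9")
r  <- lgwo_optimize(fb$fnm, fb$dim, fb$lower, fb$upper,
                    lgwo_control(n_agents = 30, max_iter = 500),
                    seed = 1, vectorized = TRUE)
r
#> LGWO run (seed 1): best fitness 4.44089e-16 after 62135 evaluations
```

The terminal value 4.44e-16 is the double-precision floor of the Ackley
function at the origin — the pack's contraction move shrinks every
coordinate until it underflows, so the optimizer lands on the exact
global minimizer.

```r
# 2. synthetic prognosis table -> feature screen -> LGWO-BP fit
d  <- sim_binary_table(n = 500, p = 50, k_informative = 5,
                       effect = 0.8, seed = 1)
fr <- rank_features(d, k = 5)
fr$selected
#> [1] "V3" "V5" "V2" "V1" "V4"

fit <- lgwo_nnet(label ~ ., fr$data, seed = 1)
fit
#> LGWO-BP network: 5-6-1, 43 parameters
#> training MSE 0.1554, training accuracy 0.818 (threshold 0.50)

summary(fit)
#> accuracy 0.818  recall 0.800  precision 0.803  F1 0.802  AUC 0.884  Brier 0.1554
#> optimizer best fitness 0.217582 in 531 evaluations (seed 1)
```

The screen recovers exactly the five planted features (their absolute
point-biserial correlations stand out from the null band ~2/√n), and the
fitted network separates the classes with AUC ≈ 0.88 on the training
table.

```r
# 3. repeated-run tables and the rank-sum comparison
tab <- run_trials("lgwo", c("f14", "f15"), n_runs = 5, base_seed = 1,
                  control = lgwo_control(20, 200))
tab[, c("fn", "best", "mean", "sd")]
#>    fn       best       mean           sd
#> 1 f14 -1.0316285 -1.0316284 8.564327e-09
#> 2 f15  0.3978875  0.3978877 1.841577e-07

# LGWO's 30 exact zeros on the sphere vs canonical GWO's finals
g <- run_trials("gwo", "f1", n_runs = 30, base_seed = 1)
ranksum_p(rep(0, 30), attr(g, "finals")$f1)
#> [1] 1.21178e-12
```

A command-line front end with the same functionality ships in
`inst/cli/levywolf` (subcommands `benchmark`, `train`, `evaluate`,
`select`, `simulate`, `compare`, `registry`).

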