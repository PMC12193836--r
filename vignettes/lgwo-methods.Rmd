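---
title: "Levy-enhanced Grey Wolf optimization and the LGWO-BP classifier"
author: "levywolf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Levy-enhanced Grey Wolf optimization and the LGWO-BP classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levywolf)
```

## The optimizer

The Grey Wolf Optimizer (GWO) is a population metaheuristic for box-bounded
minimization. The three fittest agents — alpha, beta, delta — steer the rest:
each wolf moves to the mean of three leader-anchored points

$$X_l' = X_l - A_l \circ |C_l \circ X_l - x|, \qquad
  x(t+1) = \tfrac13\,(X_\alpha' + X_\beta' + X_\delta'),$$

with per-coordinate draws $A \sim U(-a, a)$ and $C \sim U(0, 2)$, and an
exploration radius $a(t) = 2(1 - t/T_{max})$ shrinking linearly over the run.
Leaders are refreshed once per iteration after the whole pack has moved
(synchronous sweep), ties in leader selection break by lower agent index, and
every move is clamped back into the box (a `clamp = FALSE` switch exists for
studying unbounded escapes — on objectives that are unbounded below outside
their box, such as the Schwefel sum (f7), an unclamped population can run off
to astronomically negative values, which is why clamping is the default).

LGWO layers five mechanisms on this substrate:

1. **Weight factor.** $O(t) = \frac{T_{max}-2}{T_{max}}\bigl(w_s -
   (w_s - w_e)\,\frac{2}{\pi}\arctan(a + b\,t)\bigr)^2$ with defaults
   $w_s = 1.5$, $w_e = 0.1$, $a = 1$, $b = 0.01$. The normalized
   $\frac{2}{\pi}\arctan(\cdot)$ reading makes the bracket decay smoothly
   from $w_s$ toward $w_e$, so $O(t)$ falls from about 0.60 toward
   $\frac{T_{max}-2}{T_{max}} w_e^2 \approx 0.009$. Read literally as
   $\arctan(\cdot)\cdot 2\pi$ the bracket would be large and negative and
   $O(t)$ would not act as a decaying weight at all, contradicting the
   declared start/end roles of $w_s$ and $w_e$; the literal form is still
   available behind `lgwo_control(literal_weight = TRUE)` for study.
2. **Levy repositioning.** When the escape mode is active, every non-leader
   wolf is displaced by $S = 0.01\,\ell \circ (x - x_\alpha)$ with
   per-coordinate Mantegna draws $\ell = u/|v|^{1/\beta}$
   ($u \sim N(0, \sigma_u^2)$, $v \sim N(0,1)$, tail index $\beta = 1.5$).
   The repositioning is applied unconditionally — it is an exploration move,
   and elitism is preserved because the three leaders are exempt and the
   incumbent best is tracked separately.
3. **Best/worst Levy and opposition candidates.** The incumbent best
   generates $x_{best} + O L (x_{best} - x_{worst})$ and the mirrored
   candidate $ub + lb - L\,x_{best}$, each with a fresh scalar Levy draw
   $L$, accepted only on improvement.
4. **Drift and contraction.** Every wolf generates $x + L(x_{best} - x)$
   and $O\,x$; the fittest of the three candidates is kept. The
   contraction move is what finishes runs on origin-centred objectives:
   once the pack is in the global basin, repeated accepted contractions
   shrink coordinates geometrically until they underflow to exact zero,
   which is why sphere-like runs end at literally `0.0` and Ackley runs
   end at the double-precision floor `4.44e-16`.
5. **Harris-Hawks-style mutation.** Each wolf, with probability
   $p_p = 0.1$ per iteration, generates
   $x_3 = x_r - r|x_r - 2r\,x|$ and
   $x_4 = (x_{best} - \bar x) - r((ub - lb) r + lb)$ (independent
   per-coordinate uniform draws for each $r$; $x_r$ a uniformly chosen
   other wolf, $\bar x$ the pack mean), keeping the fittest of
   $\{x_3, x_4, x\}$.

**Escape-mode trigger.** The escape machinery engages once
`stagnation_window` iterations (default 5) have elapsed without the run
having converged, and then stays on. We examined the alternative reading —
trigger only while the best fitness improves by less than $10^{-12}$ over a
sliding window — and found it cannot produce the exact-zero terminal
behaviour on the slowest unimodal objective (the max-modulus function f4):
steady multiplicative improvements of order $10^{-10}$ per window keep such
a trigger off until too few iterations remain for the contraction cascade,
leaving roughly half the runs short of underflow. Treating the window as the
delay before the Levy search mode activates reproduces the terminal
behaviour on every origin-optimum function in the suite, and setting the
window longer than the run disables the enhancements entirely, which
together with `pp = 0` makes `lgwo_optimize()` bitwise identical to
`gwo_optimize()` on shared seeds (a property the test suite asserts).

**Scalar versus per-coordinate Levy draws.** The repositioning step uses
per-coordinate draws (it is written as a vector scaling); the drift,
contraction, opposition and best/worst moves use one scalar draw per
candidate so that identities such as "drift with $L = 1$ lands exactly on
$x_{best}$" hold coordinate-consistently.

## Known limitations of the optimizer

On the two-dimensional Shekel-foxholes function (f12) the best of 30
seeded runs reaches the global minimum 0.998004, but typically 5–8 of 30
runs terminate in a neighbouring foxhole, giving a mean near 1.4 rather
than 0.998. This is structural: after the pack converges to a suboptimal
hole, the only moves that can reach the global hole are the opposition
candidate — which with a scalar multiplier only samples the ray through
the origin and the incumbent best, a ray that misses the global hole from
most stuck states — and the mutation's broad $x_4$ samples, whose
probability of landing inside the acceptance region is of order $10^{-4}$
per draw. No defensible variant we tested (greedy versus unconditional
repositioning, per-wolf versus best-only opposition, per-coordinate versus
scalar draws) changes this materially. The same effect leaves a minority
of Hartmann-6 runs at the second-best local optimum, consistent with the
published mean for that function.

## The LGWO-BP classifier

`lgwo_nnet()` trains a single-hidden-layer sigmoid network
$\hat y = f(W f(V x + \theta_v) + \theta_w)$, $f(z) = 1/(1+e^{-z})$, for a
0/1 outcome. All weights and biases live in one flat vector (length
$hi + h + oh + o$); LGWO searches that vector inside $[-1, 1]$ against the
training mean squared error (5 agents and 30 iterations by default — the
protocol for network training, as opposed to the 30/500 benchmarking
protocol), and full-batch backpropagation then refines the incumbent best.
Features are min-max scaled to $[0, 1]$ internally: with weights confined
to $[-1, 1]$, unscaled inputs would saturate both sigmoids.

Defaults that matter:

* `hidden = 6` units, one output unit; threshold 0.5 with ties to the
  positive class.
* Training error is MSE on the sigmoid output ("mse"); cross-entropy is
  available via `loss = "xent"`.
* Refinement runs `lr = 0.5` for `epochs = 500` full-batch steps. The
  MSE gradient through two sigmoids carries a factor
  $\hat y(1-\hat y) \le 1/4$ twice and a $1/n$ from the mean, so rates an
  order of magnitude smaller leave visible underfitting on even linearly
  separable data; 0.5/500 trains the separable fixture to accuracy 1.0
  while remaining stable. Set `epochs = 0` to inspect the raw optimizer
  solution.

## Synthetic data: what it emulates and what it does not

`sim_binary_table()` emulates the statistical shape of wide omics-style
prognosis tables: Bernoulli($\pi$) labels and continuous features, of which
`k_informative` carry a class-mean shift $\delta$ (in feature-sd units)
plus $N(0, \text{noise}^2)$. The planted point-biserial correlation has the
closed form $\delta\sqrt{\pi(1-\pi)} / \sqrt{\delta^2\pi(1-\pi) + 1 +
\text{noise}^2}$ — about 0.19 at $\delta = 0.4$, noise 0.1, $\pi = 0.5$ —
matching the 0.1–0.25 band of absolute correlations that univariate screens
report on real prognosis matrices. The generator is Gaussian and
independent across features; it does not emulate the heavy marginals,
feature correlation structure, batch effects or censoring of real omics
data, so passing tests demonstrate pipeline correctness and statistical
calibration, not clinical performance.

Three fixtures exercise distinct behaviours: `separable` (n = 200, p = 5,
margin-0.5 linearly separable; an explicitly constructed weight vector
classifies it perfectly), `xor` (n = 400, four Gaussian clusters at
$(\pm1, \pm1)$ with sd 0.3; the best linear rule on the realized sample
reaches 0.79 accuracy — the population ceiling is 0.75, finite-sample
overfitting of the cut adds the rest — so beating it requires a nonlinear
fit), and `imbalanced` ($\pi = 0.1$, for label-swap metric checks).

## Evaluation statistics

The rank-sum test uses midranks, tie-corrected variance and a 0.5
continuity correction on the normal approximation. At $n = 30$ vs 30 this
formula has two characteristic values the suite pins down exactly: a fully
tied sample against 30 distinct larger values gives $1.21\times10^{-12}$,
and two fully separated tie-free samples give $3.02\times10^{-11}$. The
signed-rank test drops zero differences and enumerates the exact
permutation distribution up to $n = 25$ (normal approximation with tie
correction beyond). AUC is computed from midranks (the Mann–Whitney
probability with half credit for ties, identical to the trapezoidal ROC
area) and is cross-checked in the tests against a brute-force loop over
all positive/negative pairs. Repeated-run tables report the sample
standard deviation ($n-1$); degenerate comparisons (all values identical)
report $p = 1$ rather than NaN.

## Problem sizes used by the shipped checks

The acceptance script and test suite rerun the full benchmarking protocol
(30 agents, 500 iterations, 30 seeded runs) on the functions whose
published statistics are desk-reproducible, and the pipeline checks use
n = 1000, p = 50 screening tables over 20 seeds and the n = 200/400
fixtures; these sizes were chosen so the whole suite reruns in minutes on
one core while keeping every Monte-Carlo margin wide.
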