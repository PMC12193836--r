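# Independent oracles used across the suite.

# AUC by brute force over all positive/negative pairs (half credit for
# ties) -- the probabilistic definition, independent of the rank-based
# implementation.
auc_bruteforce <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  if (length(sp) == 0 || length(sn) == 0) return(NA_real_)
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# central finite-difference gradient of the MSE fitness
fd_gradient <- function(params, shape, X, y, h = 1e-6) {
  vapply(seq_along(params), function(j) {
    pp <- pm <- params
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    (mlp_fitness(pp, shape, X, y) - mlp_fitness(pm, shape, X, y)) / (2 * h)
  }, numeric(1))
}

# small random labeled set with both classes present
random_labeled <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  y <- c(0, 1, rbinom(n - 2, 1, 0.5))
  list(X = X, y = y)
}
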