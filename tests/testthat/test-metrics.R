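test_that("confusion metrics agree with their definitions", {
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  r <- classification_metrics(y, y, scores = y)
  expect_equal(r$accuracy, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$auc, 1)
  expect_equal(r$brier, 0)
  expect_equal(r$tp + r$fp + r$tn + r$fn, length(y))

  # F1 is the harmonic mean on random confusion tables
  set.seed(30)
  for (i in 1:100) {
    y <- c(0, 1, rbinom(40, 1, runif(1, 0.2, 0.8)))
    p <- c(1, 0, rbinom(40, 1, runif(1, 0.2, 0.8)))
    r <- classification_metrics(y, p)
    if (is.finite(r$precision) && is.finite(r$recall) &&
        (r$precision + r$recall) > 0)
      expect_equal(r$f1, 2 * r$precision * r$recall /
                          (r$precision + r$recall))
    expect_equal(r$accuracy, (r$tp + r$tn) / r$n)
  }
  # precision 0.88, recall 0.93 combine to F1 ~ 0.904
  expect_equal(2 * 0.88 * 0.93 / (0.88 + 0.93), 0.9043, tolerance = 1e-4)
})

test_that("rank-based AUC equals the brute-force pairwise probability", {
  expect_equal(auc_rank(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    expect_lt(abs(auc_rank(y, s) - auc_bruteforce(y, s)), 1e-12)
  }
  expect_warning(r <- classification_metrics(rep(1, 5), rep(1, 5),
                                             runif(5)), "one class")
  expect_true(is.na(r$auc))
})

test_that("label swap preserves accuracy and score-flipped AUC", {
  set.seed(32)
  y <- c(0, 1, rbinom(50, 1, 0.3))
  p <- rbinom(52, 1, 0.5)
  s <- runif(52)
  a <- classification_metrics(y, p, s)
  b <- label_swap_metrics(y, p, s)
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$auc, b$auc)
  expect_equal(a$brier, b$brier)
  # degenerate all-positive predictions: swapped recall is 0
  d <- label_swap_metrics(y, rep(1, 52), s)
  expect_equal(d$recall, 0)
})

test_that("macro and weighted averaging behave as stated", {
  r1 <- structure(list(accuracy = 0.9, recall = 0.8, precision = 0.7,
                       f1 = 0.8, auc = 0.9, brier = 0.1),
                  class = "metric_report")
  r2 <- structure(list(accuracy = 0.9, recall = 0.6, precision = 0.5,
                       f1 = 0.6, auc = 0.7, brier = 0.2),
                  class = "metric_report")
  mw <- macro_weighted(list(r1, r2), c(0.5, 0.5))
  expect_equal(unname(mw$macro), unname(mw$weighted))
  mw <- macro_weighted(list(r1, r2), c(0.9, 0.1), fields = "f1")
  expect_equal(unname(mw$weighted), 0.78)
  expect_equal(unname(mw$macro), 0.7)
  mw <- macro_weighted(list(r1, r1), c(0.3, 0.7))
  expect_equal(unname(mw$macro), unname(mw$weighted))
})

test_that("k-fold splits partition the indices evenly", {
  sp <- kfold_split(10, 5, seed = 1)
  expect_length(sp, 5)
  expect_true(all(vapply(sp, function(f) length(f$test), integer(1)) == 2L))
  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:200, 1); k <- sample(2:min(n, 10), 1)
    sp <- kfold_split(n, k, seed = i)
    tests <- lapply(sp, `[[`, "test")
    expect_equal(sort(unlist(tests)), seq_len(n))
    sizes <- lengths(tests)
    expect_lte(max(sizes) - min(sizes), 1L)
    for (f in sp) {
      expect_length(intersect(f$train, f$test), 0)
      expect_equal(sort(c(f$train, f$test)), seq_len(n))
    }
  }
  expect_identical(kfold_split(30, 5, seed = 2), kfold_split(30, 5, seed = 2))
  expect_error(kfold_split(4, 5), "k must")
})

test_that("rank-sum reproduces the n=30 fingerprint p-values", {
  # one sample fully tied at 0 vs 30 distinct positives
  p1 <- ranksum_p(rep(0, 30), seq_len(30))
  expect_equal(signif(p1, 3), 1.21e-12)
  # fully separated, tie-free
  p2 <- ranksum_p(seq_len(30), 31:60)
  expect_equal(signif(p2, 3), 3.02e-11)
  expect_equal(ranksum_p(1:10, 1:10), 1)
  expect_equal(ranksum_p(rep(2, 8), rep(2, 9)), 1)
})

test_that("rank-sum is symmetric, monotone-invariant, and matches the
           reference normal approximation", {
  set.seed(34)
  for (i in 1:25) {
    a <- round(rnorm(sample(5:30, 1)), 1)
    b <- round(rnorm(sample(5:30, 1), mean = runif(1, -1, 1)), 1)
    p <- ranksum_p(a, b)
    expect_equal(p, ranksum_p(b, a))
    expect_equal(p, ranksum_p(exp(a), exp(b)))
    ref <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    expect_equal(p, ref, tolerance = 1e-10)
  }
})

test_that("signed-rank handles exact and approximate regimes", {
  expect_equal(signed_rank_p(1:8, 1:8), 1)
  # five all-positive differences: exact two-sided p = 2/2^5
  expect_equal(signed_rank_p(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1) + 0.1),
               0.0625)
  set.seed(35)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    p <- signed_rank_p(a, b)
    expect_equal(p, signed_rank_p(b, a))          # antisymmetry
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(p, ref, tolerance = 1e-10)
  }
  a <- rnorm(40); b <- rnorm(40)
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = TRUE))$p.value
  expect_equal(signed_rank_p(a, b), ref, tolerance = 1e-10)
})

test_that("Cohen's d standardizes by the pooled sd", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means 1 and 0, both sds exactly 1, equal n -> d = 1
  a <- c(0, 1, 2); b <- c(-1, 0, 1)
  expect_equal(cohens_d(a, b), 1)
  expect_warning(d <- cohens_d(c(0, 0), c(1, 1)), "pooled")
  expect_true(is.na(d))
})

test_that("run tables aggregate per-seed finals correctly", {
  tab <- run_trials("lgwo", c("f16", "f15"), n_runs = 3, base_seed = 1,
                    control = lgwo_control(5, 20))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$best <= tab$mean))
  expect_true(all(tab$sd >= 0))
  finals <- attr(tab, "finals")
  expect_equal(tab$mean[1], mean(finals$f16))
  expect_equal(tab$sd[1], sd(finals$f16))
  one <- run_trials("gwo", "f16", n_runs = 1, base_seed = 5,
                    control = gwo_control(5, 10))
  expect_equal(one$best, one$mean)
  expect_equal(one$sd, 0)
})
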