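# Canonical Grey Wolf Optimizer. The three best agents (alpha, beta,
# delta) steer the pack: every wolf moves to the mean of three
# leader-anchored points X_i = X_leader - A_i * |C_i * X_leader - X|
# with A in [-a, a] and C in [0, 2] drawn per coordinate, and the
# exploration radius a shrinking linearly from 2 to 0 over the run.

#' Control parameters for the Grey Wolf Optimizer
#'
#' @param n_agents pack size (at least 3 so the three leaders exist).
#'   Default 30 for benchmark studies; network training uses 5.
#' @param max_iter iteration budget Tmax.
#' @param clamp clamp every move back into the box bounds. Turning this
#'   off reproduces the unbounded escape that unclamped implementations
#'   show on objectives unbounded below outside their box.
#' @param noisy treat the objective as noisy: greedy comparisons
#'   re-evaluate the incumbent instead of trusting its cached fitness.
#' @return A list of class \code{"gwo_control"}.
#' @export
gwo_control <- function(n_agents = 30L, max_iter = 500L, clamp = TRUE,
                        noisy = FALSE) {
  stopifnot(n_agents >= 3, max_iter >= 1)
  structure(list(n_agents = as.integer(n_agents),
                 max_iter = as.integer(max_iter),
                 clamp = isTRUE(clamp), noisy = isTRUE(noisy)),
            class = "gwo_control")
}

#' Linearly decaying exploration coefficient
#'
#' \eqn{a(t) = 2(1 - t/T_{max})}: 2 at the start of the run, 0 at the end.
#'
#' @param t iteration, \code{0 <= t <= Tmax}.
#' @param Tmax iteration budget.
#' @export
linear_a <- function(t, Tmax) {
  if (any(t < 0) || any(t > Tmax)) stop("t must lie in [0, Tmax]")
  2 * (1 - t / Tmax)
}

#' Draw the encircling coefficients A and C
#'
#' \eqn{A = 2 a r_1 - a} (each coordinate in \eqn{[-a, a]}) and
#' \eqn{C = 2 r_2} (each coordinate in \eqn{[0, 2]}), with
#' \eqn{r_1, r_2 \sim U(0,1)} per coordinate.
#'
#' @param a current exploration radius, \code{a >= 0}.
#' @param dim number of coordinates.
#' @return List with numeric vectors \code{A} and \code{C}.
#' @export
sample_coefficients <- function(a, dim) {
  stopifnot(a >= 0, dim >= 1)
  list(A = 2 * a * stats::runif(dim) - a, C = 2 * stats::runif(dim))
}

#' One leader-guided position update
#'
#' Computes \eqn{D_l = |C_l \circ X_l - x|} and
#' \eqn{X_l' = X_l - A_l \circ D_l} for each leader l in (alpha, beta,
#' delta) with independent coefficient draws, and returns the mean of the
#' three anchored points. \code{A} and \code{C} may be supplied as 3 x dim
#' matrices to fix the draws (used by tests); otherwise they are sampled.
#'
#' @param x current position.
#' @param x_alpha,x_beta,x_delta leader positions.
#' @param a exploration radius.
#' @param A,C optional fixed coefficient matrices (3 rows: alpha, beta,
#'   delta).
#' @return The updated position.
#' @export
leader_update <- function(x, x_alpha, x_beta, x_delta, a,
                          A = NULL, C = NULL) {
  d <- length(x)
  stopifnot(length(x_alpha) == d, length(x_beta) == d, length(x_delta) == d)
  if (is.null(A)) A <- matrix(2 * a * stats::runif(3 * d) - a, 3, d)
  if (is.null(C)) C <- matrix(2 * stats::runif(3 * d), 3, d)
  X1 <- x_alpha - A[1, ] * abs(C[1, ] * x_alpha - x)
  X2 <- x_beta  - A[2, ] * abs(C[2, ] * x_beta  - x)
  X3 <- x_delta - A[3, ] * abs(C[3, ] * x_delta - x)
  (X1 + X2 + X3) / 3
}

# vectorized pack sweep shared by gwo_optimize and lgwo_optimize; P is
# the n x d position matrix, leaders are length-d vectors. Draw order:
# (A1, C1, A2, C2, A3, C3), each a full n x d matrix.
.pack_sweep <- function(P, x_alpha, x_beta, x_delta, a) {
  n <- nrow(P); d <- ncol(P)
  anchor <- function(xl) {
    A <- matrix(2 * a * stats::runif(n * d) - a, n, d)
    C <- matrix(2 * stats::runif(n * d), n, d)
    L <- matrix(xl, n, d, byrow = TRUE)
    L - A * abs(C * L - P)
  }
  (anchor(x_alpha) + anchor(x_beta) + anchor(x_delta)) / 3
}

# coordinatewise clamp; lower/upper are scalars or length-d vectors
.clamp <- function(X, lower, upper) {
  n <- nrow(X)
  pmin(pmax(X, rep(lower, each = n)), rep(upper, each = n))
}

# wrap a user objective so a whole matrix of points can be scored;
# non-finite values become +Inf so such a wolf can never lead
.make_scorer <- function(objective, vectorized) {
  function(X) {
    f <- if (vectorized) objective(X)
    else apply(X, 1, objective)
    f[!is.finite(f)] <- Inf
    f
  }
}

# indices of the three leaders (ties break by lower index; order() is
# stable for ties)
.leader_idx <- function(fitness) order(fitness)[1:3]

.new_optresult <- function(best_position, best_fitness, curve, n_evals,
                           seed, method) {
  structure(list(best_position = best_position, best_fitness = best_fitness,
                 curve = curve, n_evals = n_evals, seed = seed,
                 method = method),
            class = "wolf_opt")
}

#' Minimize an objective with the canonical Grey Wolf Optimizer
#'
#' @param objective function of a length-\code{dim} numeric vector
#'   returning a scalar (minimized). Set \code{vectorized = TRUE} if it
#'   instead maps an n x dim matrix to an n-vector (much faster).
#' @param dim number of decision variables.
#' @param lower,upper box bounds, scalars or length-\code{dim} vectors.
#' @param control a [gwo_control()] list.
#' @param seed integer seed; the whole run is deterministic given it.
#' @param vectorized whether \code{objective} is matrix-capable.
#' @return An object of class \code{"wolf_opt"}: best position and
#'   fitness, the per-iteration best-so-far convergence curve, the
#'   evaluation count and the seed.
#' @examples
#' fb <- get_benchmark("f1")
#' r <- gwo_optimize(fb$fnm, dim = 2, lower = -100, upper = 100,
#'                   control = gwo_control(30, 200), seed = 1,
#'                   vectorized = TRUE)
#' r$best_fitness
#' @export
gwo_optimize <- function(objective, dim, lower, upper,
                         control = gwo_control(), seed = 1L,
                         vectorized = FALSE) {
  run_pack(objective, dim, lower, upper, control, seed, vectorized,
           enhanced = FALSE)
}

# shared driver for GWO and LGWO. `control` is a gwo_control or
# lgwo_control; enhanced = TRUE switches on the weight-factor / Levy /
# OBL / mutation machinery.
run_pack <- function(objective, dim, lower, upper, control, seed,
                     vectorized, enhanced) {
  stopifnot(dim >= 1, all(lower < upper))
  lower <- rep_len(lower, dim)
  upper <- rep_len(upper, dim)
  score <- .make_scorer(objective, vectorized)
  n <- control$n_agents
  Tmax <- control$max_iter
  set.seed(seed)

  P <- matrix(stats::runif(n * dim, min = rep(lower, each = n),
                           max = rep(upper, each = n)), n, dim)
  fit <- score(P)
  n_evals <- n
  li <- .leader_idx(fit)
  best_x <- P[li[1L], ]
  best_f <- fit[li[1L]]
  curve <- numeric(Tmax)
  stagnant <- FALSE

  for (t in seq_len(Tmax)) {
    a <- linear_a(t, Tmax)
    Pnew <- .pack_sweep(P, P[li[1L], ], P[li[2L], ], P[li[3L], ], a)
    if (control$clamp) Pnew <- .clamp(Pnew, lower, upper)
    P <- Pnew
    fit <- score(P)
    n_evals <- n_evals + n

    if (enhanced) {
      # after `stagnation_window` iterations the run has not converged
      # to the optimum, so the search switches to the Levy-escape mode
      # for the remainder (a window longer than the run disables it)
      stagnant <- t > control$stagnation_window
      st <- .lgwo_enhance(P, fit, best_x, best_f, t, Tmax, lower, upper,
                          control, score, stagnant)
      P <- st$P; fit <- st$fit
      best_x <- st$best_x; best_f <- st$best_f
      n_evals <- n_evals + st$evals
    }

    li <- .leader_idx(fit)
    if (fit[li[1L]] < best_f) {
      best_f <- fit[li[1L]]
      best_x <- P[li[1L], ]
    }
    curve[t] <- best_f
  }

  .new_optresult(best_x, best_f, curve, n_evals, seed,
                 if (enhanced) "lgwo" else "gwo")
}

#' @export
print.wolf_opt <- function(x, ...) {
  cat(sprintf("%s run (seed %d): best fitness %.6g after %d evaluations\n",
              toupper(x$method), x$seed, x$best_fitness, x$n_evals))
  invisible(x)
}

#' @export
summary.wolf_opt <- function(object, ...) {
  cat(sprintf("%s optimization result\n", toupper(object$method)))
  cat(sprintf("  best fitness : %.8g\n", object$best_fitness))
  cat(sprintf("  iterations   : %d\n", length(object$curve)))
  cat(sprintf("  evaluations  : %d\n", object$n_evals))
  cat(sprintf("  seed         : %d\n", object$seed))
  invisible(object)
}

#' Plot the convergence curve of an optimizer run
#'
#' @param x a \code{"wolf_opt"} result.
#' @param log plot the fitness axis on a log scale where positive.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wolf_opt <- function(x, log = TRUE, ...) {
  y <- x$curve
  uselog <- log && all(y > 0)
  graphics::plot(seq_along(y), y, type = "l",
                 log = if (uselog) "y" else "",
                 xlab = "iteration", ylab = "best-so-far fitness",
                 main = sprintf("%s convergence (seed %d)",
                                toupper(x$method), x$seed), ...)
  invisible(x)
}
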