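# Classical benchmark objectives used to exercise the optimizers: six
# unimodal functions (f1-f6), five scalable multimodal functions (f7-f11)
# and seven fixed-dimension multimodal functions (f12-f18). Each entry
# carries its dimension, a common box bound for every coordinate, and the
# literature global minimum. Evaluators are written matrix-first (rows =
# points) so a whole pack can be scored in one call.

# penalty term of the penalized multimodal function f11
.u_penalty <- function(X, a, k, m) {
  out <- matrix(0, nrow(X), ncol(X))
  hi <- X > a
  lo <- X < -a
  out[hi] <- k * (X[hi] - a)^m
  out[lo] <- k * (-X[lo] - a)^m
  out
}

# Shekel foxholes grid: 25 columns of (a1j, a2j), the classic 5x5 lattice
.foxholes_a <- local({
  g <- c(-32, -16, 0, 16, 32)
  rbind(rep(g, times = 5), rep(g, each = 5))
})

# Kowalik data: 11 observed rates a_i at inverse concentrations b_i
.kowalik_a <- c(0.1957, 0.1947, 0.1735, 0.1600, 0.0844, 0.0627,
                0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
.kowalik_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

# Hartmann-3 constants
.h3_a <- matrix(c(3, 10, 30,
                  0.1, 10, 35,
                  3, 10, 30,
                  0.1, 10, 35), 4, 3, byrow = TRUE)
.h3_c <- c(1, 1.2, 3, 3.2)
.h3_p <- matrix(c(0.3689, 0.117, 0.2673,
                  0.4699, 0.4387, 0.747,
                  0.1091, 0.8732, 0.5547,
                  0.03815, 0.5743, 0.8828), 4, 3, byrow = TRUE)

# Hartmann-6 constants
.h6_a <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                  0.05, 10, 17, 0.1, 8, 14,
                  3, 3.5, 1.7, 10, 17, 8,
                  17, 8, 0.05, 10, 0.1, 14), 4, 6, byrow = TRUE)
.h6_c <- c(1, 1.2, 3, 3.2)
.h6_p <- matrix(c(0.1312, 0.1696, 0.5569, 0.0124, 0.8283, 0.5886,
                  0.2329, 0.4135, 0.8307, 0.3736, 0.1004, 0.9991,
                  0.2348, 0.1451, 0.3522, 0.2883, 0.3047, 0.6650,
                  0.4047, 0.8828, 0.8732, 0.5743, 0.1091, 0.0381),
                4, 6, byrow = TRUE)

.hartmann <- function(X, A, C, P) {
  out <- numeric(nrow(X))
  for (i in seq_along(C)) {
    D2 <- sweep(X, 2, P[i, ])^2
    out <- out - C[i] * exp(-as.vector(D2 %*% A[i, ]))
  }
  out
}

# evaluators; X is an n x dim matrix, return length-n vector
.bench_eval <- list(
  f1 = function(X) rowSums(X^2),
  f2 = function(X) rowSums(abs(X)) + apply(abs(X), 1, prod),
  f3 = function(X) rowSums(t(apply(X, 1, cumsum))^2),
  f4 = function(X) apply(abs(X), 1, max),
  f5 = function(X) {
    d <- ncol(X)
    rowSums(100 * (X[, -1, drop = FALSE] - X[, -d, drop = FALSE]^2)^2 +
              (X[, -d, drop = FALSE] - 1)^2)
  },
  f6 = function(X) {
    d <- ncol(X)
    rowSums(sweep(X^4, 2, seq_len(d), `*`)) + stats::runif(nrow(X))
  },
  f7 = function(X) rowSums(-X * sin(sqrt(abs(X)))),
  f8 = function(X) rowSums(X^2 - 10 * cos(2 * pi * X) + 10),
  f9 = function(X) {
    d <- ncol(X)
    -20 * exp(-0.2 * sqrt(rowSums(X^2) / d)) -
      exp(rowSums(cos(2 * pi * X)) / d) + 20 + exp(1)
  },
  f10 = function(X) {
    d <- ncol(X)
    rowSums(X^2) / 4000 -
      apply(cos(sweep(X, 2, sqrt(seq_len(d)), `/`)), 1, prod) + 1
  },
  f11 = function(X) {
    d <- ncol(X)
    Xi <- X[, -d, drop = FALSE]
    Xip <- X[, -1, drop = FALSE]
    0.1 * (sin(3 * pi * X[, 1])^2 +
             rowSums((Xi - 1)^2 * (1 + sin(3 * pi * Xip)^2)) +
             (X[, d] - 1)^2 * (1 + sin(2 * pi * X[, d])^2)) +
      rowSums(.u_penalty(X, 5, 100, 4))
  },
  f12 = function(X) {
    acc <- numeric(nrow(X))
    for (j in seq_len(25)) {
      dj <- (X[, 1] - .foxholes_a[1, j])^6 + (X[, 2] - .foxholes_a[2, j])^6
      acc <- acc + 1 / (j + dj)
    }
    1 / (1 / 500 + acc)
  },
  f13 = function(X) {
    out <- numeric(nrow(X))
    for (i in seq_len(11)) {
      b <- .kowalik_b[i]
      out <- out +
        (.kowalik_a[i] - X[, 1] * (b^2 + b * X[, 2]) /
           (b^2 + b * X[, 3] + X[, 4]))^2
    }
    out
  },
  f14 = function(X) {
    x1 <- X[, 1]; x2 <- X[, 2]
    4 * x1^2 - 2.1 * x1^4 + x1^6 / 3 + x1 * x2 - 4 * x2^2 + 4 * x2^4
  },
  f15 = function(X) {
    x1 <- X[, 1]; x2 <- X[, 2]
    (x2 - 5.1 / (4 * pi^2) * x1^2 + 5 / pi * x1 - 6)^2 +
      10 * (1 - 1 / (8 * pi)) * cos(x1) + 10
  },
  f16 = function(X) {
    x1 <- X[, 1]; x2 <- X[, 2]
    (1 + (x1 + x2 + 1)^2 *
       (19 - 14 * x1 + 3 * x1^2 - 14 * x2 + 6 * x1 * x2 + 3 * x2^2)) *
      (30 + (2 * x1 - 3 * x2)^2 *
         (18 - 32 * x1 + 12 * x1^2 + 48 * x2 - 36 * x1 * x2 + 27 * x2^2))
  },
  f17 = function(X) .hartmann(X, .h3_a, .h3_c, .h3_p),
  f18 = function(X) .hartmann(X, .h6_a, .h6_c, .h6_p)
)

.bench_meta <- data.frame(
  id = paste0("f", 1:18),
  name = c("sphere", "schwefel-2.22", "schwefel-1.2", "schwefel-2.21",
           "rosenbrock", "noisy-quartic", "schwefel-2.26", "rastrigin",
           "ackley", "griewank", "penalized-2", "shekel-foxholes",
           "kowalik", "six-hump-camel", "branin", "goldstein-price",
           "hartmann-3", "hartmann-6"),
  dim = c(rep(30L, 11), 2L, 4L, 2L, 2L, 2L, 3L, 6L),
  lower = c(-100, -10, -100, -100, -30, -1.28, -500, -5.12, -32, -600, -50,
            -65, -5, -5, -5, -2, 0, 0),
  upper = c(100, 10, 100, 100, 30, 1.28, 500, 5.12, 32, 600, 50,
            65, 5, 5, 5, 2, 1, 1),
  known_optimum = c(0, 0, 0, 0, 0, 0, -12569.4866, 0, 0, 0, 0,
                    0.998004, 3.0749e-4, -1.03163, 0.397887, 3,
                    -3.86278, -3.32237),
  noisy = c(rep(FALSE, 5), TRUE, rep(FALSE, 12)),
  stringsAsFactors = FALSE
)

# known global minimizers (used by tests; f6 omitted: noisy)
.bench_argmin <- list(
  f1 = rep(0, 30), f2 = rep(0, 30), f3 = rep(0, 30), f4 = rep(0, 30),
  f5 = rep(1, 30), f6 = rep(0, 30),
  f7 = rep(420.9687, 30), f8 = rep(0, 30), f9 = rep(0, 30),
  f10 = rep(0, 30), f11 = rep(1, 30),
  f12 = c(-32, -32),
  f13 = c(0.192833, 0.190836, 0.123117, 0.135766),
  f14 = c(0.0898, -0.7126),
  f15 = c(pi, 2.275),
  f16 = c(0, -1),
  f17 = c(0.114614, 0.555649, 0.852547),
  f18 = c(0.20169, 0.150011, 0.476874, 0.275332, 0.311652, 0.6573)
)

#' Look up a benchmark objective by identifier
#'
#' Returns the full definition of one of the 18 classical test functions:
#' six unimodal, five scalable multimodal and seven fixed-dimension
#' multimodal objectives, with their dimensions, box bounds and known
#' global minima.
#'
#' @param id character identifier, one of \code{"f1"} ... \code{"f18"}.
#' @return An object of class \code{"benchmark_fn"}: a list with elements
#'   \code{id}, \code{name}, \code{dim}, \code{lower}, \code{upper},
#'   \code{known_optimum}, \code{noisy}, the vector evaluator \code{fn}
#'   and the matrix evaluator \code{fnm} (rows = points).
#' @examples
#' fb <- get_benchmark("f1")
#' fb$fn(rep(0, fb$dim))   # 0 at the origin
#' @seealso [benchmark_ids()], [benchmark_registry()], [evaluate_benchmark()]
#' @export
get_benchmark <- function(id) {
  i <- match(id, .bench_meta$id)
  if (length(id) != 1L || is.na(i))
    stop("unknown benchmark function id: ", paste(id, collapse = ", "))
  meta <- .bench_meta[i, ]
  fnm <- .bench_eval[[id]]
  out <- list(
    id = meta$id, name = meta$name, dim = meta$dim,
    lower = meta$lower, upper = meta$upper,
    known_optimum = meta$known_optimum, noisy = meta$noisy,
    fn = function(x) fnm(matrix(x, nrow = 1L))[1L],
    fnm = fnm,
    argmin = .bench_argmin[[id]]
  )
  class(out) <- "benchmark_fn"
  out
}

#' @export
print.benchmark_fn <- function(x, ...) {
  cat(sprintf("benchmark %s (%s): dim %d, bounds [%g, %g], optimum %g%s\n",
              x$id, x$name, x$dim, x$lower, x$upper, x$known_optimum,
              if (x$noisy) ", noisy" else ""))
  invisible(x)
}

#' Identifiers of all registered benchmark functions
#' @return Character vector \code{"f1"} ... \code{"f18"}.
#' @export
benchmark_ids <- function() .bench_meta$id

#' Machine-readable registry of the benchmark suite
#'
#' @return A data frame with one row per function: id, name, dimension,
#'   bounds, known optimum and the noise flag.
#' @export
benchmark_registry <- function() .bench_meta

#' Evaluate a benchmark objective
#'
#' @param fn a \code{"benchmark_fn"} from [get_benchmark()].
#' @param x numeric vector of length \code{fn$dim}, or a matrix with
#'   \code{fn$dim} columns (one point per row).
#' @return Objective value(s). For the noisy quartic (f6) the additive
#'   uniform term is drawn from the current random stream.
#' @export
evaluate_benchmark <- function(fn, x) {
  stopifnot(inherits(fn, "benchmark_fn"))
  if (is.matrix(x)) {
    if (ncol(x) != fn$dim) stop("point matrix must have ", fn$dim, " columns")
    if (any(!is.finite(x))) stop("non-finite input")
    return(fn$fnm(x))
  }
  if (length(x) != fn$dim)
    stop("expected a vector of length ", fn$dim, ", got ", length(x))
  if (any(!is.finite(x))) stop("non-finite input")
  fn$fn(x)
}
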