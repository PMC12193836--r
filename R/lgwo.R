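# LGWO: the Grey Wolf Optimizer augmented with (i) an arctan-decayed
# weight factor O(t), (ii) Levy-flight repositioning of non-leader wolves
# when the best fitness stagnates, (iii) opposition-based learning and a
# best/worst Levy move for the incumbent best, (iv) per-wolf drift and
# contraction candidates, and (v) Harris-Hawks-style mutation -- all
# candidates accepted greedily. The contraction move O * x is what
# collapses the pack onto an origin optimum down to floating-point zero.

#' Control parameters for LGWO
#'
#' Extends [gwo_control()] with the enhancement parameters. \code{ws} and
#' \code{we} are the start and end values of the weight-factor bracket
#' (1.5 and 0.1), \code{a_const}/\code{b_const} the arctan offsets (1 and
#' 0.01), \code{beta_levy} the Levy tail index, \code{levy_scale} the
#' 0.01 multiplier of the Levy repositioning step, \code{pp} the mutation
#' probability and \code{stagnation_window} the number of iterations the
#' plain Grey Wolf search is given to converge before the run switches to
#' the Levy escape machinery for the remainder.
#'
#' @inheritParams gwo_control
#' @param ws,we weight-factor start/end values, \code{0 < we < ws}.
#' @param a_const,b_const arctan argument constants.
#' @param beta_levy Levy tail index in (0, 2).
#' @param levy_scale multiplier of the Levy repositioning displacement.
#' @param pp mutation probability in [0, 1]; \code{pp = 0} disables
#'   mutation without consuming random draws.
#' @param stagnation_window iterations of plain Grey Wolf search before
#'   the Levy-escape mode engages; a window larger than \code{max_iter}
#'   disables the escape moves entirely.
#' @param literal_weight evaluate the weight factor with the literal
#'   \code{arctan(.) * 2 * pi} product instead of the normalized
#'   \code{(2/pi) * arctan(.)} reading (for study only; see
#'   [weight_factor()]).
#' @return A list of classes \code{"lgwo_control"}, \code{"gwo_control"}.
#' @export
lgwo_control <- function(n_agents = 30L, max_iter = 500L, clamp = TRUE,
                         noisy = FALSE, ws = 1.5, we = 0.1, a_const = 1,
                         b_const = 0.01, beta_levy = 1.5, levy_scale = 0.01,
                         pp = 0.1, stagnation_window = 5L,
                         literal_weight = FALSE) {
  stopifnot(0 < we, we < ws, pp >= 0, pp <= 1, stagnation_window >= 1,
            beta_levy > 0, beta_levy < 2)
  ctrl <- gwo_control(n_agents, max_iter, clamp, noisy)
  ctrl[c("ws", "we", "a_const", "b_const", "beta_levy", "levy_scale",
         "pp", "stagnation_window", "literal_weight")] <-
    list(ws, we, a_const, b_const, beta_levy, levy_scale, pp,
         as.integer(stagnation_window), isTRUE(literal_weight))
  class(ctrl) <- c("lgwo_control", "gwo_control")
  ctrl
}

#' Arctan-decayed weight factor O(t)
#'
#' \deqn{O(t) = \frac{T_{max}-2}{T_{max}}\left(w_s - (w_s - w_e)\,
#'   \frac{2}{\pi}\arctan(a + b t)\right)^2}
#' With the defaults (ws = 1.5, we = 0.1, a = 1, b = 0.01) the bracket
#' decays from ws towards we as the normalized arctan rises from 1/2
#' towards 1, so O(t) is strictly decreasing: about 0.597 at t = 0 and
#' approaching \code{(Tmax-2)/Tmax * we^2} for large t. The
#' \code{literal_weight} control flag keeps the printed
#' \code{arctan(.) * 2pi} product instead (an oscillation-prone reading
#' retained for study).
#'
#' @param t iteration.
#' @param Tmax iteration budget.
#' @param control an [lgwo_control()] list supplying ws, we, a, b.
#' @return The scalar weight O(t).
#' @export
weight_factor <- function(t, Tmax, control = lgwo_control()) {
  at <- atan(control$a_const + control$b_const * t)
  inner <- if (control$literal_weight)
    control$ws - (control$ws - control$we) * at * 2 * pi
  else
    control$ws - (control$ws - control$we) * at * 2 / pi
  (Tmax - 2) / Tmax * inner^2
}

#' Levy-flight repositioning displacement
#'
#' \eqn{S = s \cdot \ell \circ (x - x_\alpha)} with per-coordinate
#' Mantegna draws \eqn{\ell} and scale s (default 0.01). Added to a
#' stagnating wolf's position to relocate it around the leader.
#'
#' @param x wolf position.
#' @param x_alpha leader position.
#' @param control an [lgwo_control()].
#' @return The displacement vector (zero where \code{x == x_alpha}).
#' @export
levy_restart <- function(x, x_alpha, control = lgwo_control()) {
  control$levy_scale * levy_step(length(x), control$beta_levy) * (x - x_alpha)
}

#' Best/worst Levy candidate
#'
#' \eqn{x_{new} = x_{best} + O \cdot L (x_{best} - x_{worst})}; the caller
#' accepts it only if it improves on \eqn{x_{best}}.
#'
#' @param x_best,x_worst incumbent best and current worst positions.
#' @param O weight factor.
#' @param L scalar Levy draw.
#' @export
greedy_levy_update <- function(x_best, x_worst, O, L) {
  x_best + O * L * (x_best - x_worst)
}

#' Opposition-based learning candidate
#'
#' \eqn{x_{new} = ub + lb - L \cdot x_{best}} per coordinate: the
#' Levy-scaled mirror image of the incumbent best within the box.
#'
#' @param x_best incumbent best position.
#' @param lower,upper box bounds (scalars or vectors).
#' @param L scalar Levy draw.
#' @export
opposition <- function(x_best, lower, upper, L) {
  upper + lower - L * x_best
}

#' Drift candidate
#'
#' \eqn{x + L (x_{best} - x)}: a Levy-scaled move towards the incumbent
#' best (exactly \eqn{x_{best}} at L = 1, unchanged at L = 0).
#'
#' @param x wolf position.
#' @param x_best incumbent best.
#' @param L scalar Levy draw.
#' @export
drift_update <- function(x, x_best, L) {
  x + L * (x_best - x)
}

#' Contraction candidate
#'
#' \eqn{O \cdot x} per coordinate. Under greedy acceptance this move
#' shrinks converged packs geometrically onto an origin optimum, which is
#' how runs on origin-centred objectives terminate at exactly 0.
#'
#' @param x wolf position.
#' @param O weight factor.
#' @export
contraction_update <- function(x, O) {
  O * x
}

#' Harris-Hawks-style mutation candidates
#'
#' \deqn{x_3 = x_r - r_1 |x_r - 2 r_2 x|}
#' \deqn{x_4 = (x_{best} - \bar x) - r_3 ((ub - lb) r_4 + lb)}
#' with independent per-coordinate uniform draws for every occurrence of
#' r. \code{x_r} is a uniformly chosen other wolf and \eqn{\bar x} the
#' pack mean.
#'
#' @param x wolf position being mutated.
#' @param x_r another wolf's position.
#' @param x_best incumbent best.
#' @param x_mean arithmetic mean of all current positions.
#' @param lower,upper box bounds.
#' @param rand optional list of the four uniform draw vectors
#'   (\code{r1}..\code{r4}), fixed by tests.
#' @return List with candidates \code{x3} and \code{x4}.
#' @export
hho_mutation <- function(x, x_r, x_best, x_mean, lower, upper,
                         rand = NULL) {
  d <- length(x)
  if (is.null(rand))
    rand <- list(r1 = stats::runif(d), r2 = stats::runif(d),
                 r3 = stats::runif(d), r4 = stats::runif(d))
  list(x3 = x_r - rand$r1 * abs(x_r - 2 * rand$r2 * x),
       x4 = (x_best - x_mean) - rand$r3 * ((upper - lower) * rand$r4 + lower))
}

# One round of the LGWO enhancements, applied after the base sweep of
# iteration t. `stagnant` gates the Levy-escape block (repositioning,
# best/worst Levy and opposition candidates, drift/contraction);
# mutation runs every iteration when pp > 0. All candidate moves except
# the Levy repositioning are accepted greedily. Returns the updated
# pack, its fitnesses, the (possibly improved) incumbent best, and the
# evaluation count.
.lgwo_enhance <- function(P, fit, best_x, best_f, t, Tmax, lower, upper,
                          control, score, stagnant) {
  n <- nrow(P); d <- ncol(P)
  evals <- 0L
  clampv <- function(x) if (control$clamp) pmin(pmax(x, lower), upper) else x
  eval1 <- function(x) { evals <<- evals + 1L; score(matrix(x, 1L)) }
  incumbent <- function(i) {
    # fitness of wolf i used in greedy comparisons
    if (control$noisy) { evals <<- evals + 1L; score(P[i, , drop = FALSE]) }
    else fit[i]
  }

  if (stagnant) {
    O <- weight_factor(t, Tmax, control)
    li <- .leader_idx(fit)

    # Levy repositioning of all non-leader wolves: an exploration move,
    # applied unconditionally (the three leaders are exempt and the
    # incumbent best is tracked separately, so elitism is preserved)
    others <- setdiff(seq_len(n), li)
    if (length(others)) {
      S <- control$levy_scale *
        matrix(levy_step(length(others) * d, control$beta_levy),
               length(others), d) *
        sweep(P[others, , drop = FALSE], 2, P[li[1L], ])
      cand <- .clamp2(P[others, , drop = FALSE] + S, lower, upper,
                      control$clamp)
      P[others, ] <- cand
      fit[others] <- score(cand); evals <- evals + length(others)
    }

    # best/worst Levy move and opposition for the incumbent best, greedy
    worst <- P[which.max(fit), ]
    cand <- clampv(greedy_levy_update(best_x, worst, O, levy_step(1, control$beta_levy)))
    cf <- eval1(cand)
    if (cf < best_f) { best_x <- cand; best_f <- cf }
    cand <- clampv(opposition(best_x, lower, upper, levy_step(1, control$beta_levy)))
    cf <- eval1(cand)
    if (cf < best_f) { best_x <- cand; best_f <- cf }

    # drift and contraction candidates per wolf, keep the fittest
    L <- levy_step(n, control$beta_levy)
    X1 <- .clamp2(P + L * (matrix(best_x, n, d, byrow = TRUE) - P),
                  lower, upper, control$clamp)
    X2 <- .clamp2(O * P, lower, upper, control$clamp)
    f1 <- score(X1); f2 <- score(X2); evals <- evals + 2L * n
    f0 <- if (control$noisy) { evals <- evals + n; score(P) } else fit
    take2 <- f2 < pmin(f0, f1)
    take1 <- !take2 & f1 < f0
    P[take1, ] <- X1[take1, , drop = FALSE]; fit[take1] <- f1[take1]
    P[take2, ] <- X2[take2, , drop = FALSE]; fit[take2] <- f2[take2]
  }

  # Harris-Hawks-style mutation, each wolf with probability pp
  if (control$pp > 0) {
    q <- stats::runif(n)
    hit <- which(q < control$pp)
    if (length(hit)) {
      x_mean <- colMeans(P)
      for (i in hit) {
        j <- sample(seq_len(n)[-i], 1L)
        m <- hho_mutation(P[i, ], P[j, ], best_x, x_mean, lower, upper)
        x3 <- clampv(m$x3); x4 <- clampv(m$x4)
        f3 <- eval1(x3); f4 <- eval1(x4)
        f0 <- incumbent(i)
        if (f3 <= f4 && f3 < f0) { P[i, ] <- x3; fit[i] <- f3 }
        else if (f4 < f3 && f4 < f0) { P[i, ] <- x4; fit[i] <- f4 }
      }
    }
  }

  list(P = P, fit = fit, best_x = best_x, best_f = best_f, evals = evals)
}

.clamp2 <- function(X, lower, upper, do) {
  if (!do) return(X)
  .clamp(X, lower, upper)
}

#' Minimize an objective with LGWO
#'
#' Runs the canonical Grey Wolf sweep every iteration and, once the run
#' has not converged within \code{stagnation_window} iterations, layers
#' on the Levy-flight escape machinery for the remainder: unconditional
#' Levy repositioning of the non-leader wolves, then the best/worst Levy
#' and opposition candidates for the incumbent best and per-wolf drift
#' and contraction candidates under greedy acceptance. Independently,
#' every wolf mutates with probability \code{pp} via the
#' Harris-Hawks-style candidates. With \code{pp = 0} and a stagnation
#' window longer than the run, LGWO consumes exactly the same random
#' draws as [gwo_optimize()] and reproduces it bitwise.
#'
#' @inheritParams gwo_optimize
#' @param control an [lgwo_control()] list.
#' @return An object of class \code{"wolf_opt"}; see [gwo_optimize()].
#' @examples
#' fb <- get_benchmark("f9")
#' r <- lgwo_optimize(fb$fnm, dim = 5, lower = fb$lower, upper = fb$upper,
#'                    control = lgwo_control(20, 150), seed = 1,
#'                    vectorized = TRUE)
#' r$best_fitness
#' @export
lgwo_optimize <- function(objective, dim, lower, upper,
                          control = lgwo_control(), seed = 1L,
                          vectorized = FALSE) {
  stopifnot(inherits(control, "lgwo_control"))
  run_pack(objective, dim, lower, upper, control, seed, vectorized,
           enhanced = TRUE)
}
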