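# Mantegna's construction for Levy-stable step lengths: a ratio of
# normals u / |v|^(1/beta) with a beta-dependent scale on u realizes the
# heavy-tailed law L(s) ~ |s|^(-1-beta). The optimizer uses these steps
# for its stagnation-escape moves.

#' Mantegna scale for the Levy-step numerator normal
#'
#' Closed form
#' \deqn{\sigma_u = \left[\frac{\Gamma(1+\beta)\,\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta}}
#' so that \eqn{u/|v|^{1/\beta}} with \eqn{u \sim N(0,\sigma_u^2)},
#' \eqn{v \sim N(0,1)} has the Levy tail index \eqn{\beta}.
#'
#' @param beta tail index in (0, 2). \code{beta = 2} is degenerate
#'   (\eqn{\sigma_u = 0}, the Gaussian edge of the stable family) and is
#'   rejected for sampling.
#' @return The positive scale \eqn{\sigma_u} (zero at \code{beta = 2}).
#' @examples
#' mantegna_sigma(1)    # exactly 1
#' mantegna_sigma(1.5)
#' @export
mantegna_sigma <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta > 2)
    stop("beta must lie in (0, 2]")
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Draw Levy-distributed steps by the Mantegna algorithm
#'
#' Each draw is \eqn{u / |v|^{1/\beta}} with \eqn{u \sim N(0,\sigma_u^2)}
#' and \eqn{v \sim N(0,1)}; the sign of the step comes from \eqn{u}.
#' Deterministic given the state of R's random stream.
#'
#' @param n number of draws.
#' @param beta tail index in (0, 2); default 1.5, the cuckoo-search
#'   convention.
#' @return Numeric vector of \code{n} heavy-tailed steps.
#' @export
levy_step <- function(n, beta = 1.5) {
  if (beta >= 2) stop("beta must be < 2 for sampling (beta = 2 is degenerate)")
  sigma <- mantegna_sigma(beta)
  u <- stats::rnorm(n, 0, sigma)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}
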