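# Single-hidden-layer sigmoid network. The whole parameter set (input
# weights v, hidden biases, output weights w, output bias) lives in one
# flat vector so a population optimizer can search it directly; the
# layout is [v by hidden unit | theta_v | w by output unit | theta_w].

#' Network shape descriptor
#'
#' @param n_in number of input features.
#' @param n_hidden hidden units (default 6).
#' @param n_out output units (1 for binary tasks).
#' @return List of class \code{"mlp_shape"} with the counts and the
#'   total parameter count \code{n_params}.
#' @export
mlp_shape <- function(n_in, n_hidden = 6L, n_out = 1L) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 n_out = as.integer(n_out),
                 n_params = n_params(n_in, n_hidden, n_out)),
            class = "mlp_shape")
}

#' Number of free parameters of a single-hidden-layer network
#'
#' \code{h*i + h + o*h + o}: input weights, hidden biases, output
#' weights, output biases.
#'
#' @param n_in,n_hidden,n_out layer sizes (or pass an \code{"mlp_shape"}
#'   as \code{n_in}).
#' @export
n_params <- function(n_in, n_hidden = 6L, n_out = 1L) {
  if (inherits(n_in, "mlp_shape")) return(n_in$n_params)
  as.integer(n_hidden * n_in + n_hidden + n_out * n_hidden + n_out)
}

#' Numerically stable logistic sigmoid
#'
#' \eqn{1/(1+e^{-x})}, evaluated branch-wise so neither tail overflows.
#'
#' @param x numeric vector or matrix.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# split the flat vector into the weight/bias blocks
.decode_params <- function(params, shape) {
  i <- shape$n_in; h <- shape$n_hidden; o <- shape$n_out
  stopifnot(length(params) == shape$n_params)
  k <- 0L
  V <- matrix(params[k + seq_len(h * i)], h, i, byrow = TRUE); k <- k + h * i
  bV <- params[k + seq_len(h)]; k <- k + h
  W <- matrix(params[k + seq_len(o * h)], o, h, byrow = TRUE); k <- k + o * h
  bW <- params[k + seq_len(o)]
  list(V = V, bV = bV, W = W, bW = bW)
}

.encode_params <- function(blocks) {
  c(as.vector(t(blocks$V)), blocks$bV, as.vector(t(blocks$W)), blocks$bW)
}

#' Forward pass of the sigmoid network
#'
#' \eqn{Y = f(W f(V x + \theta_v) + \theta_w)} with the logistic sigmoid
#' at both layers.
#'
#' @param params flat parameter vector of length
#'   \code{n_params(shape)}.
#' @param shape an [mlp_shape()].
#' @param X numeric matrix (n samples x \code{n_in} features).
#' @return n x \code{n_out} matrix of outputs, all strictly in (0, 1).
#' @export
mlp_forward <- function(params, shape, X) {
  X <- as.matrix(X)
  if (ncol(X) != shape$n_in)
    stop("X has ", ncol(X), " columns; network expects ", shape$n_in)
  b <- .decode_params(params, shape)
  H <- sigmoid(sweep(X %*% t(b$V), 2, b$bV, `+`))
  sigmoid(sweep(H %*% t(b$W), 2, b$bW, `+`))
}

#' Training error of a parameter vector
#'
#' Mean squared error between the network outputs and the 0/1 labels --
#' the fitness the optimizer minimizes. Cross-entropy is available as an
#' alternative loss.
#'
#' @inheritParams mlp_forward
#' @param y numeric 0/1 label vector of length \code{nrow(X)}.
#' @param loss \code{"mse"} (default) or \code{"xent"}.
#' @export
mlp_fitness <- function(params, shape, X, y, loss = c("mse", "xent")) {
  loss <- match.arg(loss)
  if (NROW(X) == 0L) stop("empty data")
  out <- mlp_forward(params, shape, X)
  if (loss == "mse") mean((out - y)^2)
  else -mean(y * log(out) + (1 - y) * log(1 - out))
}

# analytic gradient of the MSE loss wrt the flat vector (full batch)
.mlp_grad <- function(params, shape, X, y) {
  X <- as.matrix(X)
  n <- nrow(X); o <- shape$n_out
  b <- .decode_params(params, shape)
  Hpre <- sweep(X %*% t(b$V), 2, b$bV, `+`)
  H <- sigmoid(Hpre)
  Opre <- sweep(H %*% t(b$W), 2, b$bW, `+`)
  out <- sigmoid(Opre)
  # dL/dOpre for L = mean over n*o of (out - y)^2
  dO <- 2 * (out - y) * out * (1 - out) / (n * o)
  gW <- t(dO) %*% H
  gbW <- colSums(dO)
  dH <- (dO %*% b$W) * H * (1 - H)
  gV <- t(dH) %*% X
  gbV <- colSums(dH)
  .encode_params(list(V = gV, bV = gbV, W = gW, bW = gbW))
}

#' Backpropagation refinement
#'
#' Full-batch gradient descent on the MSE training error through both
#' sigmoid layers, started from \code{params}. This is the local
#' refinement stage of the LGWO-BP hybrid.
#'
#' @inheritParams mlp_fitness
#' @param lr learning rate (\code{lr = 0} returns \code{params}
#'   unchanged).
#' @param epochs number of full-batch steps.
#' @return The refined flat parameter vector.
#' @export
bp_refine <- function(params, shape, X, y, lr = 0.5, epochs = 500L) {
  stopifnot(lr >= 0, epochs >= 0)
  if (lr == 0 || epochs == 0) return(params)
  for (e in seq_len(epochs))
    params <- params - lr * .mlp_grad(params, shape, X, y)
  params
}

#' Threshold network outputs into class labels
#'
#' @inheritParams mlp_forward
#' @param threshold decision threshold in (0, 1]; outputs \code{>=}
#'   threshold map to class 1 (ties go to the positive class).
#' @return Integer 0/1 vector (first output unit).
#' @export
mlp_predict <- function(params, shape, X, threshold = 0.5) {
  as.integer(mlp_forward(params, shape, X)[, 1L] >= threshold)
}
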