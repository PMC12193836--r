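# LGWO-BP: the hybrid classifier. A wolf pack searches the network's
# flat weight vector globally inside [-1, 1] against the MSE training
# error, then full-batch backpropagation refines the incumbent best.
# Defaults follow the training protocol: 5 agents, 30 iterations,
# bounds +/-1, 6 hidden units.

#' Fit a binary classifier by Levy-enhanced Grey Wolf optimization of a
#' sigmoid network
#'
#' Trains a single-hidden-layer sigmoid network for a 0/1 outcome by
#' global search over the flat weight/bias vector with LGWO (or the
#' canonical GWO baseline), followed by backpropagation refinement of
#' the best solution (the "-BP" stage). Features are min-max scaled to
#' [0, 1] internally (weights are confined to [-1, 1], so unbounded
#' inputs would saturate the sigmoid); the scaling is stored and
#' re-applied by \code{predict}.
#'
#' @param formula model formula, e.g. \code{label ~ .}; the response
#'   must be coded 0/1 (or a two-level factor).
#' @param data data frame holding the variables.
#' @param x,y alternative matrix interface: numeric feature matrix and
#'   0/1 label vector (used when \code{formula} is missing).
#' @param hidden hidden-layer size (default 6).
#' @param optimizer \code{"lgwo"} (default) or \code{"gwo"}.
#' @param n_agents,max_iter pack size and iteration budget of the
#'   global-search stage (defaults 5 and 30).
#' @param lower,upper search bounds for every weight and bias
#'   (defaults -1 and 1).
#' @param lr,epochs backpropagation refinement settings; \code{epochs =
#'   0} skips refinement so the fit is the optimizer's best position.
#' @param threshold decision threshold for class 1.
#' @param loss training error: \code{"mse"} (default) or \code{"xent"}.
#' @param seed integer seed; the fit is deterministic given it.
#' @param ... passed on to [lgwo_control()] / [gwo_control()].
#' @return An object of class \code{"lgwo_nnet"} with components
#'   \code{params} (trained flat vector), \code{shape}, \code{scaling},
#'   \code{opt} (the \code{"wolf_opt"} trace), \code{fitted.values}
#'   (training-set probabilities), and the call. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{plot} (the
#'   optimizer convergence curve), \code{residuals}.
#' @examples
#' d <- sim_fixtures()$separable
#' fit <- lgwo_nnet(label ~ ., d, seed = 1)
#' mean(predict(fit, d) == d$label)   # training accuracy
#' @export
lgwo_nnet <- function(formula, data, x, y, hidden = 6L,
                      optimizer = c("lgwo", "gwo"), n_agents = 5L,
                      max_iter = 30L, lower = -1, upper = 1, lr = 0.5,
                      epochs = 500L, threshold = 0.5,
                      loss = c("mse", "xent"), seed = 1L, ...) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  cl <- match.call()

  if (!missing(formula)) {
    mf <- stats::model.frame(formula, data)
    yv <- stats::model.response(mf)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    X <- as.matrix(x)
    yv <- y
  }
  if (is.factor(yv)) yv <- as.integer(yv) - 1L
  yv <- as.numeric(yv)
  if (!all(yv %in% c(0, 1))) stop("response must be binary 0/1")
  if (anyNA(X) || anyNA(yv)) stop("missing values are not supported")

  # per-column min-max scaling to [0, 1]; constant columns map to 0
  cmin <- apply(X, 2, min)
  crng <- apply(X, 2, max) - cmin
  crng[crng == 0] <- 1
  Xs <- sweep(sweep(X, 2, cmin), 2, crng, `/`)

  shape <- mlp_shape(ncol(Xs), hidden, 1L)
  obj <- function(p) mlp_fitness(p, shape, Xs, yv, loss = loss)
  ctrl <- if (optimizer == "lgwo")
    lgwo_control(n_agents = n_agents, max_iter = max_iter, ...)
  else gwo_control(n_agents = n_agents, max_iter = max_iter, ...)
  opt <- if (optimizer == "lgwo")
    lgwo_optimize(obj, shape$n_params, lower, upper, ctrl, seed = seed)
  else gwo_optimize(obj, shape$n_params, lower, upper, ctrl, seed = seed)

  params <- bp_refine(opt$best_position, shape, Xs, yv, lr = lr,
                      epochs = epochs)

  fitted <- mlp_forward(params, shape, Xs)[, 1L]
  out <- list(params = params, shape = shape,
              scaling = list(min = cmin, range = crng,
                             names = colnames(X)),
              opt = opt, optimizer = optimizer, threshold = threshold,
              loss = loss,
              fitted.values = fitted, y = yv,
              training_error = mean((fitted - yv)^2),
              call = cl)
  class(out) <- "lgwo_nnet"
  out
}

# apply the stored min-max scaling to new data
.nnet_newdata <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    nm <- object$scaling$names
    keep <- intersect(nm, colnames(newdata))
    if (length(keep) != length(nm))
      stop("newdata is missing columns: ",
           paste(setdiff(nm, keep), collapse = ", "))
    X <- as.matrix(newdata[, nm, drop = FALSE])
  } else X <- as.matrix(newdata)
  sweep(sweep(X, 2, object$scaling$min), 2, object$scaling$range, `/`)
}

#' Predict method for LGWO-BP network fits
#'
#' @param object an \code{"lgwo_nnet"} fit.
#' @param newdata data frame or matrix of features; the training data's
#'   min-max scaling is re-applied.
#' @param type \code{"class"} for 0/1 labels (default) or \code{"prob"}
#'   for the sigmoid output.
#' @param threshold decision threshold; defaults to the one stored in
#'   the fit.
#' @param ... unused.
#' @export
predict.lgwo_nnet <- function(object, newdata, type = c("class", "prob"),
                              threshold = NULL, ...) {
  type <- match.arg(type)
  if (is.null(threshold)) threshold <- object$threshold
  Xs <- .nnet_newdata(object, newdata)
  p <- mlp_forward(object$params, object$shape, Xs)[, 1L]
  if (type == "prob") p else as.integer(p >= threshold)
}

#' @export
print.lgwo_nnet <- function(x, ...) {
  cat(sprintf("%s-BP network: %d-%d-%d, %d parameters\n",
              toupper(x$optimizer), x$shape$n_in, x$shape$n_hidden,
              x$shape$n_out, x$shape$n_params))
  cat(sprintf("training MSE %.4f, training accuracy %.3f (threshold %.2f)\n",
              x$training_error,
              mean((x$fitted.values >= x$threshold) == (x$y == 1)),
              x$threshold))
  invisible(x)
}

#' @export
summary.lgwo_nnet <- function(object, ...) {
  print(object)
  pred <- as.integer(object$fitted.values >= object$threshold)
  rep <- classification_metrics(object$y, pred, object$fitted.values)
  cat(sprintf("accuracy %.3f  recall %.3f  precision %.3f  F1 %.3f  AUC %s  Brier %.4f\n",
              rep$accuracy, rep$recall, rep$precision, rep$f1,
              ifelse(is.na(rep$auc), "NA", sprintf("%.3f", rep$auc)),
              rep$brier))
  cat(sprintf("optimizer best fitness %.6g in %d evaluations (seed %d)\n",
              object$opt$best_fitness, object$opt$n_evals, object$opt$seed))
  invisible(rep)
}

#' @export
coef.lgwo_nnet <- function(object, ...) {
  b <- .decode_params(object$params, object$shape)
  names(b) <- c("input_weights", "hidden_bias", "output_weights",
                "output_bias")
  b
}

#' @export
residuals.lgwo_nnet <- function(object, ...) {
  object$y - object$fitted.values
}

#' @export
plot.lgwo_nnet <- function(x, ...) {
  plot(x$opt, ...)
}
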