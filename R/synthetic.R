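# Seeded generators emulating the statistical shape of omics-style
# prognosis tables: wide continuous feature matrices with a binary
# outcome in which a few features carry weak class-mean shifts. The
# planted point-biserial correlation is
#   |r| = delta * sqrt(pi (1 - pi)) / sqrt(delta^2 pi (1 - pi) + 1 + noise^2)
# so the defaults land in the ~0.1-0.25 importance range typical of
# univariate screens on such data.

#' Generate a labeled synthetic feature table
#'
#' Labels are Bernoulli(\code{balance}); the first
#' \code{k_informative} features are \eqn{N(\delta \cdot y, 1)} plus
#' \eqn{N(0, noise^2)}; the remaining features are independent
#' \eqn{N(0, 1)} noise.
#'
#' @param n number of samples.
#' @param p number of features.
#' @param k_informative number of label-shifted features,
#'   \code{<= p}.
#' @param effect class mean shift \eqn{\delta} in units of feature sd.
#' @param noise sd of additional feature noise.
#' @param balance positive-class probability \eqn{\pi} in (0, 1).
#' @param seed integer seed; the table is deterministic given it.
#' @return Data frame with numeric columns \code{V1..Vp} (informative
#'   features first) and an integer 0/1 \code{label} column.
#' @export
sim_binary_table <- function(n = 500L, p = 50L, k_informative = 5L,
                             effect = 0.5, noise = 0.1, balance = 0.5,
                             seed = 1L) {
  stopifnot(k_informative <= p, balance > 0, balance < 1, effect >= 0,
            n >= 2)
  set.seed(seed)
  y <- stats::rbinom(n, 1L, balance)
  X <- matrix(stats::rnorm(n * p), n, p)
  if (k_informative > 0) {
    shift <- matrix(effect * y, n, k_informative)
    X[, seq_len(k_informative)] <- X[, seq_len(k_informative)] + shift +
      matrix(stats::rnorm(n * k_informative, 0, noise), n, k_informative)
  }
  d <- as.data.frame(X)
  colnames(d) <- paste0("V", seq_len(p))
  d$label <- y
  d
}

#' Built-in fixture datasets
#'
#' Three seeded tables exercising distinct classifier behaviours:
#' \describe{
#'   \item{separable}{n = 200, p = 5, linearly separable: labels are a
#'     thresholded linear score of the features with a guaranteed
#'     margin.}
#'   \item{xor}{n = 400, 2 informative features in an XOR layout (four
#'     Gaussian clusters at \eqn{(\pm 1, \pm 1)}, label =
#'     sign agreement); no linear rule exceeds ~0.75 accuracy.}
#'   \item{imbalanced}{n = 500, p = 10, positive rate 0.1, for
#'     label-swap metric checks.}
#' }
#'
#' @return Named list of data frames, each with a 0/1 \code{label}
#'   column.
#' @export
sim_fixtures <- function() {
  # separable: label from the sign of a fixed linear score; points too
  # close to the separating plane are pushed away by a fixed margin
  set.seed(401L)
  n <- 200L; p <- 5L
  X <- matrix(stats::rnorm(n * p), n, p)
  w <- c(1, -0.8, 0.6, 0.4, -1.2)
  s <- as.vector(X %*% w)
  y <- as.integer(s >= 0)
  margin <- 0.5
  bump <- pmax(margin - abs(s), 0) * sign(s + (s == 0))
  X <- X + outer(bump / sum(w^2), w)   # shift along w to enforce |s| >= margin
  separable <- as.data.frame(X)
  colnames(separable) <- paste0("V", seq_len(p))
  separable$label <- y

  set.seed(402L)
  n <- 400L
  cx <- sample(c(-1, 1), n, replace = TRUE)
  cy <- sample(c(-1, 1), n, replace = TRUE)
  xor <- data.frame(V1 = cx + stats::rnorm(n, 0, 0.3),
                    V2 = cy + stats::rnorm(n, 0, 0.3),
                    label = as.integer(cx * cy > 0))

  imbalanced <- sim_binary_table(n = 500L, p = 10L, k_informative = 3L,
                                 effect = 0.8, noise = 0.1, balance = 0.1,
                                 seed = 403L)
  list(separable = separable, xor = xor, imbalanced = imbalanced)
}

#' Write a labeled table to CSV
#'
#' Comma-separated, header row, \code{label} as last column, no row
#' names; the dialect expected by [read_labeled_csv()].
#'
#' @param data data frame with a \code{label} column.
#' @param path output file.
#' @export
write_labeled_csv <- function(data, path) {
  stopifnot("label" %in% colnames(data))
  data <- data[, c(setdiff(colnames(data), "label"), "label")]
  # 17 significant digits so doubles survive the round trip bit-exactly
  out <- data
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled table from CSV
#'
#' @param path CSV file with numeric feature columns and a 0/1
#'   \code{label} column; missing values are rejected.
#' @return Data frame with the \code{label} column last.
#' @export
read_labeled_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"label" %in% colnames(d)) stop("file has no `label` column: ", path)
  if (anyNA(d)) stop("missing values in ", path)
  if (!all(d$label %in% c(0, 1))) stop("`label` column must be 0/1")
  d[, c(setdiff(colnames(d), "label"), "label")]
}
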