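# Univariate feature screening: absolute Pearson correlation between
# each feature and the 0/1 outcome (identical to the point-biserial
# correlation), ranked and truncated to the top k.

#' Pearson correlation with degenerate-input handling
#'
#' Sample Pearson correlation; a zero-variance input yields \code{NA}
#' rather than an error (the ranking step treats it as importance 0).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Rank features by absolute correlation with the outcome and keep the
#' top k
#'
#' Importance is \eqn{|r|} between each feature column and the 0/1
#' label (the point-biserial correlation). Sorting is stable: tied
#' importances keep the original column order. Constant features score
#' 0 and are flagged.
#'
#' @param data data frame with numeric feature columns and a 0/1
#'   \code{label} column (or supply \code{labels} separately).
#' @param k number of features to keep, \code{1 <= k <= p}.
#' @param labels optional label vector when \code{data} has no
#'   \code{label} column.
#' @return A list of class \code{"feature_ranking"}: \code{ranking}
#'   (data frame with \code{feature}, \code{importance},
#'   \code{constant}, all p features in rank order), \code{selected}
#'   (the top-k names) and \code{data} (the reduced data frame with the
#'   selected columns plus \code{label}).
#' @examples
#' d <- sim_binary_table(n = 200, p = 10, k_informative = 2,
#'                       effect = 1, seed = 1)
#' rank_features(d, k = 2)$selected
#' @export
rank_features <- function(data, k, labels = NULL) {
  if (is.null(labels)) {
    if (!"label" %in% colnames(data)) stop("data must have a `label` column")
    labels <- data$label
    feats <- data[, setdiff(colnames(data), "label"), drop = FALSE]
  } else feats <- data
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  p <- ncol(feats)
  if (k < 1 || k > p) stop("k must lie in [1, ", p, "]")
  imp <- vapply(feats, function(col) {
    r <- pearson_r(as.numeric(col), labels)
    if (is.na(r)) 0 else abs(r)
  }, numeric(1))
  const <- vapply(feats, function(col) stats::sd(as.numeric(col)) == 0,
                  logical(1))
  ord <- order(-imp)   # stable: ties keep column order
  ranking <- data.frame(feature = colnames(feats)[ord],
                        importance = unname(imp[ord]),
                        constant = unname(const[ord]),
                        stringsAsFactors = FALSE)
  sel <- ranking$feature[seq_len(k)]
  reduced <- cbind(feats[, sel, drop = FALSE], label = labels)
  structure(list(ranking = ranking, selected = sel, k = k,
                 data = reduced),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("top %d of %d features by |Pearson r| with the outcome:\n",
              x$k, nrow(x$ranking)))
  print(utils::head(x$ranking, x$k), row.names = FALSE)
  invisible(x)
}
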