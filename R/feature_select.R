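# Entropy / information-gain scoring over discretized descriptors, and
# top-k feature selection.

#' Shannon entropy of a label vector
#'
#' `H(T) = -sum_i P_i log2 P_i` over the empirical class distribution, with
#' `0 log 0 = 0`.  Reported in bits (log base 2 — the usual convention for
#' information-gain ranking; the base only rescales all scores identically).
#'
#' @param labels Non-empty vector of categorical labels.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c("A", "A", "B", "B"))  # 1 bit
entropy <- function(labels) {
  if (length(labels) == 0L) mt_validation_error("labels must be non-empty")
  if (anyNA(labels)) mt_validation_error("labels must not contain NA")
  p <- tabulate(factor(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a discretized feature
#'
#' `IG(T, a) = H(T) - H(T | a)`, the reduction in label entropy obtained by
#' conditioning on the feature's bins: `H(T|a) = sum_b (n_b / n) H(T in bin b)`.
#'
#' @param feature_bins Vector of bin indices (the discretized feature).
#' @param labels Vector of class labels, same length.
#' @return Information gain in bits (non-negative, at most `entropy(labels)`).
#' @export
info_gain <- function(feature_bins, labels) {
  n <- length(labels)
  if (length(feature_bins) != n)
    mt_validation_error("feature and labels must have equal length")
  h <- entropy(labels)
  cond <- 0
  for (b in unique(feature_bins)) {
    in_b <- feature_bins == b
    cond <- cond + sum(in_b) / n * entropy(labels[in_b])
  }
  h - cond
}

#' Rank descriptors by information gain and keep the top k
#'
#' Scores every column of the (continuous, typically normalized) matrix by
#' the information gain of its discretized values against the labels, sorts
#' descending (ties broken by original column order) and returns the
#' continuous matrix restricted to the first `k` columns.  Downstream steps
#' (PCA/t-SNE, the classifiers) consume the continuous values; discretization
#' is used only to score which descriptors carry label information.
#'
#' @param matrix Continuous descriptor matrix.
#' @param labels Class labels, one per row.
#' @param k Number of columns to retain (default 170).
#' @param spec [discretization_spec()] used for scoring.
#' @return A list with `matrix` (the selected columns), `features` (their
#'   names in rank order) and `scores` (a data.frame `feature`, `gain`,
#'   `rank` covering every input column).
#' @export
rank_and_select <- function(matrix, labels, k = 170L, spec = discretization_spec()) {
  check_matrix(matrix, "matrix")
  check_number(k, "select.k", lower = 1, integer = TRUE)
  if (length(labels) != nrow(matrix))
    mt_validation_error("labels must have one entry per matrix row")
  if (k > ncol(matrix))
    mt_validation_error("select.k (", k, ") exceeds the number of columns (",
                        ncol(matrix), ")")
  bins <- discretize(matrix, spec)
  gains <- vapply(seq_len(ncol(bins)),
                  function(j) info_gain(bins[, j], labels), 0)
  ord <- order(-gains, seq_along(gains))   # ties -> original column order
  scores <- data.frame(
    feature = colnames(matrix)[ord],
    gain = gains[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  sel <- ord[seq_len(k)]
  mt_log("feature selection (InfoGain): ", ncol(matrix), " -> ", k, " descriptors")
  list(matrix = matrix[, sel, drop = FALSE],
       features = colnames(matrix)[sel],
       scores = scores)
}
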