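# Significance/fold-change filtering, min-max normalization, and
# discretization used by the information-gain scorer.

#' Filter specification
#'
#' Candidate biomarkers are kept when their differential-abundance p-value is
#' at most `p_max` and the fold change is at least `fc_min`; both thresholds
#' are inclusive.
#'
#' @param p_max Maximum p-value (default 0.05).
#' @param fc_min Minimum fold change (default 1.2).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(p_max = 0.05, fc_min = 1.2) {
  check_number(p_max, "filter.p_max", lower = 0, upper = 1, open_lower = TRUE)
  check_number(fc_min, "filter.fc_min", lower = 0, open_lower = TRUE)
  structure(list(p_max = p_max, fc_min = fc_min), class = "filter_spec")
}

#' Filter a metabolite table by significance and fold change
#'
#' Retains exactly the records with `p_value <= p_max` and
#' `fold_change >= fc_min` (inclusive on both sides), preserving order.
#'
#' @param table A [metabolite_table()].
#' @param spec A [filter_spec()].
#' @return The filtered table (a warning is raised if it is empty).
#' @export
filter_significance <- function(table, spec = filter_spec()) {
  stopifnot(inherits(table, "metabolite_table"), inherits(spec, "filter_spec"))
  if (nrow(table) == 0L) mt_validation_error("table is empty")
  keep <- table$p_value <= spec$p_max & table$fold_change >= spec$fc_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("metabolite_table", "data.frame")
  mt_log("filter (p <= ", spec$p_max, ", FC >= ", spec$fc_min, "): ",
         nrow(table), " -> ", nrow(out), " records")
  if (nrow(out) == 0L)
    warning("no records pass the significance/fold-change filter")
  out
}

#' Fit column-wise min-max normalization
#'
#' Stores the per-column minimum and maximum of the training matrix; applying
#' the state maps each descriptor linearly onto `[0, 1]`.
#'
#' @param matrix Numeric descriptor matrix.
#' @return A list of class `normalization_state` with `col_ids`, `min`, `max`.
#' @export
fit_normalization <- function(matrix) {
  check_matrix(matrix, "matrix")
  structure(list(
    col_ids = colnames(matrix),
    min = apply(matrix, 2L, min),
    max = apply(matrix, 2L, max)
  ), class = "normalization_state")
}

#' Apply min-max normalization
#'
#' Maps each cell to `(x - min) / (max - min)` with the fitted column
#' statistics.  Constant columns (`max == min`) map to 0.  Values from a new
#' matrix falling outside the fitted range are clipped to `[0, 1]`; the clip
#' count is logged and attached as attribute `clipped`.
#'
#' @param matrix Numeric matrix whose columns match the fitted state.
#' @param state A [fit_normalization()] state.
#' @return The normalized matrix.
#' @export
apply_normalization <- function(matrix, state) {
  check_matrix(matrix, "matrix")
  stopifnot(inherits(state, "normalization_state"))
  if (!is.null(state$col_ids) && !identical(colnames(matrix), state$col_ids))
    mt_validation_error("column ids do not match the fitted normalization state")
  rng <- state$max - state$min
  out <- sweep(matrix, 2L, state$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  out[, !nz] <- 0
  n_clip <- sum(out < 0 | out > 1)
  if (n_clip > 0L) {
    out[out < 0] <- 0
    out[out > 1] <- 1
    mt_log("normalization clipped ", n_clip, " out-of-range cell(s)")
  }
  attr(out, "clipped") <- n_clip
  out
}

#' Discretization specification
#'
#' @param n_bins Number of ordinal bins per column (default 10, minimum 2).
#' @param strategy `"equal_width"` (default) or `"equal_frequency"`.
#' @return A list of class `discretization_spec`.
#' @export
discretization_spec <- function(n_bins = 10L, strategy = c("equal_width", "equal_frequency")) {
  check_number(n_bins, "discretize.n_bins", lower = 2, integer = TRUE)
  strategy <- match.arg(strategy)
  structure(list(n_bins = as.integer(n_bins), strategy = strategy),
            class = "discretization_spec")
}

#' Discretize a matrix into ordinal bins
#'
#' Each column is binned independently into indices `0 .. n_bins - 1`.
#' `equal_width` partitions `[min, max]` into equal intervals, left-closed
#' and right-open except the top interval, which is closed (so an interior
#' boundary value goes to the upper bin).  `equal_frequency` assigns by
#' empirical rank (ties broken by first occurrence).  A constant column maps
#' to bin 0 everywhere.
#'
#' @param matrix Numeric matrix with finite values.
#' @param spec A [discretization_spec()].
#' @return Integer matrix of bin indices with the input's dimnames.
#' @export
discretize <- function(matrix, spec = discretization_spec()) {
  check_matrix(matrix, "matrix")
  stopifnot(inherits(spec, "discretization_spec"))
  if (any(!is.finite(matrix))) mt_validation_error("matrix values must be finite")
  n <- nrow(matrix)
  nb <- spec$n_bins
  strategy <- spec$strategy
  if (strategy == "equal_frequency" && nb > n) {
    warning("n_bins exceeds the number of rows; falling back to equal_width")
    strategy <- "equal_width"
  }
  out <- matrix(0L, n, ncol(matrix), dimnames = dimnames(matrix))
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    lo <- min(x); hi <- max(x)
    if (hi == lo) next
    if (strategy == "equal_width") {
      idx <- floor((x - lo) / (hi - lo) * nb)
      idx[idx >= nb] <- nb - 1L      # top boundary belongs to the last bin
    } else {
      r <- rank(x, ties.method = "first")
      idx <- floor((r - 1) * nb / n)
    }
    out[, j] <- as.integer(idx)
  }
  out
}
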