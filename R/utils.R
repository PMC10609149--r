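# Internal helpers: argument checking, logging, seed plumbing.

mt_stop <- function(..., class = "metabotree_error") {
  stop(errorCondition(paste0(...), class = c(class, "metabotree_error")))
}

mt_validation_error <- function(...) mt_stop(..., class = "metabotree_validation_error")
mt_format_error     <- function(...) mt_stop(..., class = "metabotree_format_error")
mt_capability_error <- function(...) mt_stop(..., class = "metabotree_capability_error")

#' Toggle pipeline logging
#'
#' Log lines (record counts after filtering, feature counts before/after
#' selection, per-stage accuracies, overall-accuracy inputs) are emitted with
#' [message()] when logging is on.
#'
#' @param on `TRUE` to emit log lines, `FALSE` to silence them.
#' @return The previous setting, invisibly.
#' @export
mt_verbose <- function(on = TRUE) {
  old <- getOption("metabotree.verbose", TRUE)
  options(metabotree.verbose = isTRUE(on))
  invisible(old)
}

mt_log <- function(...) {
  if (isTRUE(getOption("metabotree.verbose", TRUE))) {
    message("[metabotree] ", ...)
  }
  invisible(NULL)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Expand one root seed into reproducible per-component seeds (kept < 2^31).
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  x <- as.double(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + as.double(abs(k)) + 1) %% 2147483647
  }
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    mt_validation_error(name, " must be a single finite number")
  if (integer && x != round(x))
    mt_validation_error(name, " must be an integer")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    mt_validation_error(name, " must be in ", if (open_lower) "(" else "[",
                        lower, ", ", upper, if (open_upper) ")" else "]",
                        " (got ", x, ")")
  invisible(x)
}

check_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    mt_validation_error(name, " must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) == 0L)
    mt_validation_error(name, " must be non-empty")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
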