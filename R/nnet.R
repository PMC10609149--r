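# R-side surface of the feedforward classifier: configuration, learning-rate
# schedule, seeded initialization, training, prediction and grid search.
# The compute kernel lives in src/mlp.cpp.

#' MLP configuration
#'
#' Defaults follow the tuned hyperparameters of the two-stage classifier:
#' three hidden layers of 300, 400 and 300 ReLU units, dropout 0.5, Adam,
#' initial learning rate 0.01 decaying exponentially (rate 0.96, capped at
#' 10000 decay steps), 500 epochs.  Training is full batch, so one epoch is
#' one optimizer step.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param dropout Dropout rate on hidden activations, in `[0, 1)`.
#' @param lr0 Initial learning rate.
#' @param decay_rate Exponential decay factor per step, in `(0, 1]`.
#' @param decay_steps Step at which the decay is capped.
#' @param epochs Number of training epochs.
#' @param seed Integer seed (weight init and dropout masks).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(300L, 400L, 300L), dropout = 0.5,
                       lr0 = 0.01, decay_rate = 0.96, decay_steps = 10000L,
                       epochs = 500L, seed = 1L,
                       optimizer = c("adam", "sgd")) {
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1 | hidden_sizes != round(hidden_sizes)))
    mt_validation_error("mlp.hidden_sizes must be positive integers")
  check_number(dropout, "mlp.dropout", lower = 0, upper = 1, open_upper = TRUE)
  check_number(lr0, "mlp.lr0", lower = 0, open_lower = TRUE)
  check_number(decay_rate, "mlp.decay_rate", lower = 0, upper = 1, open_lower = TRUE)
  check_number(decay_steps, "mlp.decay_steps", lower = 1, integer = TRUE)
  check_number(epochs, "mlp.epochs", lower = 0, integer = TRUE)
  check_number(seed, "mlp.seed", integer = TRUE)
  optimizer <- match.arg(optimizer)
  structure(list(hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
                 lr0 = lr0, decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = optimizer),
            class = "mlp_config")
}

#' Exponentially decayed learning rate
#'
#' `lr = lr0 * decay_rate^min(step, decay_steps)`: the rate decays by a
#' constant factor per optimizer step until `decay_steps`, after which it is
#' held constant.  Monotone non-increasing in `step`.
#'
#' @param step Optimizer step, starting at 0.
#' @param lr0 Initial learning rate (default 0.01).
#' @param decay_rate Decay factor (default 0.96).
#' @param decay_steps Cap on the decay exponent (default 10000).
#' @return The learning rate at `step` (vectorized over `step`).
#' @export
#' @examples
#' lr_schedule(0)    # 0.01
#' lr_schedule(10)   # 0.01 * 0.96^10
lr_schedule <- function(step, lr0 = 0.01, decay_rate = 0.96, decay_steps = 10000L) {
  if (any(step < 0)) mt_validation_error("step must be non-negative")
  lr0 * decay_rate^pmin(step, decay_steps)
}

#' Initialize an (untrained) MLP
#'
#' Builds the feedforward architecture `input_dim -> hidden_sizes ->
#' n_classes` with Glorot-uniform weights and zero biases, seeded so that the
#' same seed reproduces identical initial weights.
#'
#' @param input_dim Number of input features.
#' @param n_classes Number of output classes (>= 2).
#' @param config An [mlp_config()].
#' @param class_levels Optional character vector of class names, used to
#'   label prediction output.
#' @return A list of class `trained_mlp` (with empty training history).
#' @export
mlp_init <- function(input_dim, n_classes, config = mlp_config(),
                     class_levels = NULL) {
  check_number(input_dim, "input_dim", lower = 1, integer = TRUE)
  check_number(n_classes, "n_classes", lower = 2, integer = TRUE)
  stopifnot(inherits(config, "mlp_config"))
  sizes <- as.integer(c(input_dim, config$hidden_sizes, n_classes))
  params <- with_seed(config$seed, cpp_mlp_init(sizes))
  structure(list(
    W = params$W, b = params$b,
    input_dim = as.integer(input_dim),
    n_classes = as.integer(n_classes),
    class_levels = class_levels %||% paste0("class", seq_len(n_classes)),
    config = config,
    history = data.frame(epoch = integer(0), loss = numeric(0),
                         accuracy = numeric(0)),
    trained = FALSE
  ), class = "trained_mlp")
}

#' Train an MLP
#'
#' Full-batch minimization of the categorical cross-entropy with inverted
#' dropout on the hidden activations and the exponential learning-rate
#' schedule of [lr_schedule()].  Deterministic given the config seed.
#' `epochs = 0` returns the model unchanged.
#'
#' @param model A [mlp_init()] model.
#' @param X Numeric matrix (rows = samples, columns = `input_dim` features).
#' @param y Class labels (factor or coercible); at least 2 classes must be
#'   represented unless the model was initialized with explicit
#'   `class_levels`.
#' @param config Optional [mlp_config()] overriding the model's config.
#' @return The trained model, with per-epoch `history` (loss, training
#'   accuracy measured on the dropout forward pass).
#' @export
mlp_train <- function(model, X, y, config = NULL) {
  stopifnot(inherits(model, "trained_mlp"))
  config <- config %||% model$config
  stopifnot(inherits(config, "mlp_config"))
  check_matrix(X, "X")
  if (ncol(X) != model$input_dim)
    mt_validation_error("X has ", ncol(X), " columns; model expects ", model$input_dim)
  y <- factor(as.character(y), levels = model$class_levels)
  if (anyNA(y))
    mt_validation_error("y contains labels outside the model's class levels")
  if (length(y) != nrow(X)) mt_validation_error("X and y lengths differ")
  if (config$epochs == 0L) return(model)
  if (nlevels(droplevels(y)) < 2L)
    mt_validation_error("training data must contain at least 2 classes")
  fit <- with_seed(derive_seed(config$seed, 7L), cpp_mlp_train(
    model$W, model$b, X, as.integer(y) - 1L, model$n_classes,
    config$dropout, config$lr0, config$decay_rate, config$decay_steps,
    config$epochs, config$optimizer == "adam"
  ))
  model$W <- fit$W
  model$b <- fit$b
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = fit$loss, accuracy = fit$accuracy)
  model$config <- config
  model$trained <- TRUE
  model
}

#' Predict with a trained MLP
#'
#' Dropout is disabled at inference, so predictions are a pure function of
#' the inputs.  Ties in the argmax resolve to the lower class index.
#'
#' @param model A `trained_mlp`.
#' @param X Numeric matrix with `input_dim` columns.
#' @return A list with `labels` (factor) and `probabilities` (rows sum to 1).
#' @export
mlp_predict <- function(model, X) {
  stopifnot(inherits(model, "trained_mlp"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  check_matrix(X, "X")
  if (ncol(X) != model$input_dim)
    mt_validation_error("X has ", ncol(X), " columns; model expects ", model$input_dim)
  probs <- cpp_mlp_predict(model$W, model$b, X)
  probs <- probs / rowSums(probs)   # exact unit rows in double precision
  colnames(probs) <- model$class_levels
  rownames(probs) <- rownames(X)
  idx <- apply(probs, 1L, which.max)   # which.max ties -> lowest index
  list(labels = factor(model$class_levels[idx], levels = model$class_levels),
       probabilities = probs)
}

#' Grid search over MLP hyperparameters
#'
#' Evaluates the exhaustive Cartesian product of the candidate lists by
#' stratified k-fold cross-validated mean accuracy.  The best combination is
#' the highest mean; ties resolve to the first combination in product order.
#' A combination that fails to train is recorded with score 0 (with a
#' warning) and the search continues.
#'
#' @param grid Named list mapping [mlp_config()] fields to candidate lists
#'   (e.g. `list(hidden_sizes = list(c(50), c(300, 400, 300)), dropout =
#'   c(0, 0.5))`).
#' @param X,y Training data.
#' @param k_folds Number of CV folds (default 5).
#' @param seed Root seed for fold assignment and fits.
#' @param base_config Config supplying the fields not searched over.
#' @return A list with `best_config` and `table` (one row per combination,
#'   with its mean CV accuracy).
#' @export
grid_search <- function(grid, X, y, k_folds = 5L, seed = 1L,
                        base_config = mlp_config()) {
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid)))
    mt_validation_error("grid must be a non-empty named list")
  bad <- setdiff(names(grid), names(base_config))
  if (length(bad) > 0L)
    mt_validation_error("unknown mlp config field(s) in grid: ",
                        paste(bad, collapse = ", "))
  y <- factor(y)
  combos <- expand.grid(lapply(grid, seq_along), KEEP.OUT.ATTRS = FALSE)
  folds <- make_folds(y, k_folds, seed = derive_seed(seed, 11L), stratified = TRUE)
  scores <- numeric(nrow(combos))
  desc <- character(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    cfg_args <- unclass(base_config)
    for (f in names(grid)) {
      cand <- grid[[f]]
      cfg_args[[f]] <- if (is.list(cand)) cand[[combos[ci, f]]] else cand[combos[ci, f]]
    }
    cfg <- do.call(mlp_config, cfg_args)
    desc[ci] <- paste(vapply(names(grid), function(f)
      paste0(f, "=", paste(cfg_args[[f]], collapse = "x")), ""), collapse = ", ")
    acc <- tryCatch({
      fold_acc <- vapply(seq_len(k_folds), function(fi) {
        te <- folds == fi
        m <- mlp_init(ncol(X), nlevels(y), cfg, class_levels = levels(y))
        m <- mlp_train(m, X[!te, , drop = FALSE], y[!te], cfg)
        mean(mlp_predict(m, X[te, , drop = FALSE])$labels == y[te])
      }, 0)
      mean(fold_acc)
    }, error = function(e) {
      warning("grid combination ", desc[ci], " failed to train: ",
              conditionMessage(e))
      0
    })
    scores[ci] <- acc
  }
  best <- which.max(scores)   # ties -> first in product order
  cfg_args <- unclass(base_config)
  for (f in names(grid)) {
    cand <- grid[[f]]
    cfg_args[[f]] <- if (is.list(cand)) cand[[combos[best, f]]] else cand[combos[best, f]]
  }
  list(best_config = do.call(mlp_config, cfg_args),
       table = data.frame(combination = desc, mean_accuracy = scores,
                          stringsAsFactors = FALSE))
}
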