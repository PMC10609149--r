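# The two-stage tree classifier (stage 1: NS vs SC on all rows; stage 2:
# AD vs SQ on NS rows), the naive multiclass baseline, the evaluation
# protocols (stratified k-fold CV, independent test set) and the
# class-fraction-weighted overall-accuracy combiner.

#' Combine stage accuracies into the overall accuracy
#'
#' `overall = sc_frac * stage1_acc + ns_frac * stage1_acc * stage2_acc`:
#' an SC sample is correct when stage 1 is correct; an NS sample must
#' survive both stages (error propagation), so the stage accuracies
#' multiply, weighted by the class fractions.
#'
#' @param stage1_acc Accuracy of the NS/SC classifier, in `[0, 1]`.
#' @param stage2_acc Accuracy of the AD/SQ classifier, in `[0, 1]`.
#' @param ns_frac,sc_frac Fractions of NS and SC samples (must sum to 1).
#' @return The overall accuracy.
#' @export
#' @examples
#' overall_accuracy(0.962, 0.911, 0.487, 0.513)  # ~0.920
overall_accuracy <- function(stage1_acc, stage2_acc, ns_frac, sc_frac) {
  for (v in list(stage1_acc = stage1_acc, stage2_acc = stage2_acc,
                 ns_frac = ns_frac, sc_frac = sc_frac))
    check_number(v, "accuracy/fraction", lower = 0, upper = 1)
  if (abs(ns_frac + sc_frac - 1) > 1e-9)
    mt_validation_error("ns_frac + sc_frac must equal 1 (got ",
                        ns_frac + sc_frac, ")")
  sc_frac * stage1_acc + ns_frac * stage1_acc * stage2_acc
}

# Seeded (optionally stratified) k-fold assignment.  Returns an integer
# vector of fold ids 1..k.  Stratification balances each class across folds
# to within one sample.
make_folds <- function(labels, k, seed = NULL, stratified = TRUE) {
  check_number(k, "eval.k_folds", lower = 2, integer = TRUE)
  labels <- factor(labels)
  n <- length(labels)
  if (k > n) mt_validation_error("k_folds exceeds the number of samples")
  with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      small <- levels(labels)[table(labels) < k]
      if (length(small) > 0L)
        mt_validation_error("class(es) with fewer than k samples under ",
                            "stratified folding: ", paste(small, collapse = ", "),
                            "; use a smaller k or stratified = FALSE")
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- rep_len(sample(k), length(idx))
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
    folds
  })
}

# Resolve the per-stage dimensionality-reduction settings from the pipeline
# config.
stage_settings <- function(config, stage) {
  sc <- config[[stage]]
  list(dimred = sc$dimred,
       n_components = sc$n_components %||% 3L,
       tsne = sc$tsne,
       oos = sc$oos %||% "transductive")
}

# Fit one stage's chain (normalize -> select -> dimred -> classify) on the
# training partition and, when `x_test` is given, produce test predictions
# under the stage's out-of-sample policy.  Under transductive t-SNE the
# train and test rows are embedded jointly (test labels unseen).
stage_run <- function(x_train, y_train, x_test, config, stage, seed) {
  st <- stage_settings(config, stage)
  y_train <- factor(as.character(y_train))
  levels_y <- levels(y_train)
  if (length(levels_y) < 2L)
    mt_validation_error("stage ", stage, " training data has a single class")

  norm <- fit_normalization(x_train)
  xtr <- apply_normalization(x_train, norm)
  sel <- rank_and_select(xtr, y_train, k = config$select$k, spec = config$discretize)
  xtr_s <- sel$matrix
  xte_s <- NULL
  if (!is.null(x_test)) {
    xte <- apply_normalization(x_test, norm)
    xte_s <- xte[, sel$features, drop = FALSE]
  }

  mlp_cfg <- config$mlp
  mlp_cfg$seed <- derive_seed(seed, 3L)
  emb_train <- emb_test <- NULL
  pca_model <- NULL
  if (st$dimred == "pca") {
    pca_model <- pca_fit(xtr_s, st$n_components)
    emb_train <- pca_transform(pca_model, xtr_s)$coords
    if (!is.null(xte_s)) emb_test <- pca_transform(pca_model, xte_s)$coords
  } else {
    tcfg <- st$tsne
    tcfg$seed <- derive_seed(seed, 2L)
    tcfg <- do.call(tsne_config, tcfg)
    if (st$oos == "transductive" && !is.null(xte_s)) {
      joint <- tsne_embed(rbind(xtr_s, xte_s), tcfg)
      emb_train <- joint$coords[seq_len(nrow(xtr_s)), , drop = FALSE]
      emb_test <- joint$coords[nrow(xtr_s) + seq_len(nrow(xte_s)), , drop = FALSE]
    } else {
      emb <- tsne_embed(xtr_s, tcfg)
      emb_train <- emb$coords
      if (!is.null(xte_s))
        emb_test <- tsne_knn_map(xtr_s, emb_train, xte_s, kappa = 5L)
    }
  }

  model <- mlp_init(ncol(emb_train), length(levels_y), do.call(mlp_config, mlp_cfg),
                    class_levels = levels_y)
  model <- mlp_train(model, emb_train, y_train)
  train_pred <- mlp_predict(model, emb_train)
  test_pred <- if (!is.null(emb_test)) mlp_predict(model, emb_test) else NULL

  structure(list(
    norm = norm, features = sel$features, scores = sel$scores,
    dimred = st$dimred, oos = st$oos, pca_model = pca_model,
    x_selected = xtr_s, emb_train = emb_train, y_train = y_train,
    tsne = st$tsne, mlp = model, seed = seed,
    config = config, stage = stage,
    train_pred = train_pred, test_pred = test_pred,
    emb_test = emb_test
  ), class = "stage_pipeline")
}

# Predict a fitted stage on new rows of the raw descriptor matrix.
# PCA and knn-map policies reuse the stored states; transductive t-SNE
# re-embeds the stored training rows jointly with the new rows and retrains
# the classifier on the training partition with the stored seeds
# (deterministic).
stage_predict <- function(stage, x_new) {
  stopifnot(inherits(stage, "stage_pipeline"))
  xn <- apply_normalization(x_new, stage$norm)
  xn_s <- xn[, stage$features, drop = FALSE]
  if (stage$dimred == "pca") {
    emb <- pca_transform(stage$pca_model, xn_s)$coords
    return(mlp_predict(stage$mlp, emb))
  }
  if (stage$oos == "knn_map") {
    emb <- tsne_knn_map(stage$x_selected, stage$emb_train, xn_s, kappa = 5L)
    return(mlp_predict(stage$mlp, emb))
  }
  # transductive: joint embedding of the stored (already selected/normalized)
  # training rows with the new rows, then a seeded retrain on the train part
  tcfg <- stage$tsne
  tcfg$seed <- derive_seed(stage$seed, 2L)
  tcfg <- do.call(tsne_config, tcfg)
  joint <- tsne_embed(rbind(stage$x_selected, xn_s), tcfg)
  ntr <- nrow(stage$x_selected)
  emb_train <- joint$coords[seq_len(ntr), , drop = FALSE]
  emb_new <- joint$coords[ntr + seq_len(nrow(xn_s)), , drop = FALSE]
  mlp_cfg <- stage$config$mlp
  mlp_cfg$seed <- derive_seed(stage$seed, 3L)
  model <- mlp_init(ncol(emb_train), nlevels(stage$y_train),
                    do.call(mlp_config, mlp_cfg),
                    class_levels = levels(stage$y_train))
  model <- mlp_train(model, emb_train, stage$y_train)
  mlp_predict(model, emb_new)
}

#' Fit the two-stage tree classifier
#'
#' Stage 1 (NS vs SC) is fitted on every training row; stage 2 (AD vs SQ)
#' only on the rows whose top label is NS and whose subtype is known.  Each
#' stage runs its own normalize -> select -> dimred -> classify chain, with
#' feature selection scored against that stage's labels.
#'
#' @param train A [labeled_dataset()] with at least 2 samples each of NS and
#'   SC, and within NS at least 2 each of AD and SQ.
#' @param config A [pipeline_config()].
#' @param seed Root seed (default: `config$seed`).
#' @return A `two_stage_model`.
#' @export
fit_two_stage <- function(train, config = pipeline_config(), seed = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  config <- validate_config(config)
  seed <- seed %||% config$seed
  x <- train$descriptors
  top <- train$top_labels
  sub <- train$sub_labels

  counts <- c(NS = sum(top == "NS"), SC = sum(top == "SC"),
              AD = sum(sub == "AD"), SQ = sum(sub == "SQ"))
  short <- names(counts)[counts < 2L]
  if (length(short) > 0L)
    mt_validation_error("class(es) with fewer than 2 training samples: ",
                        paste(short, collapse = ", "))

  ns_rows <- which(top == "NS" & sub != "NONE")
  stage1 <- stage_run(x, top, NULL, config, "stage1", derive_seed(seed, 101L))
  stage2 <- stage_run(x[ns_rows, , drop = FALSE], droplevels(sub[ns_rows]),
                      NULL, config, "stage2", derive_seed(seed, 202L))
  structure(list(stage1 = stage1, stage2 = stage2, config = config,
                 seed = seed, n_train = nrow(x)),
            class = "two_stage_model")
}

#' Predict with a two-stage model
#'
#' Every sample receives a stage-1 (NS/SC) prediction; samples predicted SC
#' terminate at stage 1, samples predicted NS take the stage-2 (AD/SQ)
#' label.  The returned trace records both stage predictions and the number
#' of stages each sample visited, and carries a stage-2 call for every row
#' (used by the conditional stage-2 accuracy in evaluation).
#'
#' @param model A [fit_two_stage()] model.
#' @param X Descriptor matrix with the training columns.
#' @param stage_preds Optional precomputed list with elements `stage1` and
#'   `stage2` ([mlp_predict()]-shaped) for these rows; used internally by the
#'   CV driver to avoid re-embedding.
#' @return A list of class `two_stage_prediction`: `labels` (factor in
#'   SC/AD/SQ) and `trace` (data.frame).
#' @export
predict_two_stage <- function(model, X, stage_preds = NULL) {
  stopifnot(inherits(model, "two_stage_model"))
  check_matrix(X, "X")
  if (is.null(stage_preds)) {
    stage_preds <- list(stage1 = stage_predict(model$stage1, X),
                        stage2 = stage_predict(model$stage2, X))
  }
  p1 <- stage_preds$stage1
  p2 <- stage_preds$stage2
  s1 <- as.character(p1$labels)
  s2 <- as.character(p2$labels)
  final <- ifelse(s1 == "SC", "SC", s2)
  trace <- data.frame(
    name = rownames(X) %||% as.character(seq_len(nrow(X))),
    stage1_pred = s1,
    p_sc = p1$probabilities[, "SC"],
    stage2_pred = s2,
    p_ad = p2$probabilities[, "AD"],
    final = final,
    n_stages = ifelse(s1 == "SC", 1L, 2L),
    stringsAsFactors = FALSE
  )
  structure(list(labels = factor(final, levels = c("SC", "AD", "SQ")),
                 trace = trace),
            class = "two_stage_prediction")
}

new_report <- function(s1, s2, ns_frac, sc_frac, protocol,
                       baseline = NA_real_, baseline_sd = NA_real_,
                       folds = NULL, confusion = NULL) {
  s1m <- mean(s1); s2m <- mean(s2, na.rm = TRUE)
  rep <- structure(list(
    stage1_acc = s1m, stage1_sd = stats::sd(s1),
    stage2_acc = s2m, stage2_sd = stats::sd(s2[!is.na(s2)]),
    ns_frac = ns_frac, sc_frac = sc_frac,
    overall_acc = overall_accuracy(s1m, s2m, ns_frac, sc_frac),
    baseline_multiclass_acc = baseline,
    baseline_multiclass_sd = baseline_sd,
    protocol = protocol, per_fold = folds, confusion = confusion
  ), class = "evaluation_report")
  mt_log(sprintf(
    "%s: stage1 %.3f, stage2 %.3f, NS%% %.3f, SC%% %.3f -> overall %.3f%s",
    protocol, s1m, s2m, ns_frac, sc_frac, rep$overall_acc,
    if (is.na(baseline)) "" else sprintf(" (naive multiclass %.3f)", baseline)))
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> protocol:", x$protocol, "\n")
  cat(sprintf("  stage 1 (NS/SC): %.3f +/- %.3f\n", x$stage1_acc,
              x$stage1_sd %||% NA))
  cat(sprintf("  stage 2 (AD/SQ): %.3f +/- %.3f\n", x$stage2_acc,
              x$stage2_sd %||% NA))
  cat(sprintf("  class fractions: NS %.3f / SC %.3f\n", x$ns_frac, x$sc_frac))
  cat(sprintf("  overall accuracy: %.3f\n", x$overall_acc))
  if (!is.na(x$baseline_multiclass_acc))
    cat(sprintf("  naive multiclass baseline: %.3f\n", x$baseline_multiclass_acc))
  invisible(x)
}

resolve_fractions <- function(config, top_labels) {
  ns <- config$eval$ns_frac_override
  sc <- config$eval$sc_frac_override
  if (is.null(ns) || is.null(sc)) {
    ns <- mean(top_labels == "NS")
    sc <- mean(top_labels == "SC")
  }
  list(ns = ns, sc = sc)
}

# Fit + evaluate both stages for one train/test split, embedding test rows
# under the configured out-of-sample policy (jointly with the training rows
# for transductive t-SNE, labels hidden).  Stage 2's test partition is every
# held-out row, so routed rows always have an AD/SQ call; its accuracy is
# scored only on held-out rows whose true top label is NS.
two_stage_split_eval <- function(data, train_idx, test_idx, config, seed) {
  x <- data$descriptors
  top <- data$top_labels
  sub <- data$sub_labels
  ns_tr <- intersect(train_idx, which(top == "NS" & sub != "NONE"))
  stage1 <- stage_run(x[train_idx, , drop = FALSE], top[train_idx],
                      x[test_idx, , drop = FALSE], config, "stage1",
                      derive_seed(seed, 101L))
  stage2 <- stage_run(x[ns_tr, , drop = FALSE], droplevels(sub[ns_tr]),
                      x[test_idx, , drop = FALSE], config, "stage2",
                      derive_seed(seed, 202L))
  model <- structure(list(stage1 = stage1, stage2 = stage2, config = config,
                          seed = seed, n_train = length(train_idx)),
                     class = "two_stage_model")
  pred <- predict_two_stage(model, x[test_idx, , drop = FALSE],
                            stage_preds = list(stage1 = stage1$test_pred,
                                               stage2 = stage2$test_pred))
  is_ns <- top[test_idx] == "NS" & sub[test_idx] != "NONE"
  list(
    model = model, pred = pred,
    stage1_acc = mean(pred$trace$stage1_pred == as.character(top[test_idx])),
    stage2_acc = if (any(is_ns)) {
      mean(pred$trace$stage2_pred[is_ns] == as.character(sub[test_idx][is_ns]))
    } else NA_real_,
    leaf_true = leaf_labels(top[test_idx], sub[test_idx]),
    leaf_pred = pred$labels
  )
}

#' Cross-validate the two-stage classifier
#'
#' Splits the data into `k` folds (stratified by leaf class by default so no
#' fold loses a class), fits the full two-stage chain on each training
#' partition and scores the held-out fold: stage-1 accuracy on all test
#' rows, stage-2 accuracy on test rows whose true top label is NS.  The
#' overall accuracy combines the fold-mean stage accuracies with the full
#' dataset's class fractions (or the configured overrides).
#'
#' @param data A [labeled_dataset()].
#' @param k Number of folds (default 5).
#' @param config A [pipeline_config()].
#' @param seed Root seed (default `config$eval$seed`).
#' @param stratified Stratify folds by leaf class (default `TRUE`).
#' @param baseline Also fit the naive multiclass baseline on the same folds
#'   (default `FALSE`).
#' @return An `evaluation_report` (protocol `"cv5"`-style) with per-fold
#'   accuracies and the pooled 3-class confusion matrix of the routed
#'   predictions.
#' @export
cross_validate <- function(data, k = 5L, config = pipeline_config(),
                           seed = NULL, stratified = TRUE, baseline = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  config <- validate_config(config)
  seed <- seed %||% config$eval$seed
  leaf <- leaf_labels(data$top_labels, data$sub_labels)
  folds <- make_folds(leaf, k, seed = derive_seed(seed, 1L),
                      stratified = stratified)
  s1 <- s2 <- base_acc <- numeric(k)
  conf <- NULL
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    res <- two_stage_split_eval(data, train_idx, test_idx, config,
                                derive_seed(seed, 1000L + f))
    s1[f] <- res$stage1_acc
    s2[f] <- res$stage2_acc
    tab <- table(true = res$leaf_true, predicted = res$leaf_pred)
    conf <- if (is.null(conf)) tab else conf + tab
    if (baseline) {
      base_acc[f] <- naive_split_eval(data, train_idx, test_idx, config,
                                      derive_seed(seed, 2000L + f))$accuracy
    }
  }
  fr <- resolve_fractions(config, data$top_labels)
  new_report(s1, s2, fr$ns, fr$sc, protocol = paste0("cv", k),
             baseline = if (baseline) mean(base_acc) else NA_real_,
             baseline_sd = if (baseline) stats::sd(base_acc) else NA_real_,
             folds = data.frame(fold = seq_len(k), stage1_acc = s1,
                                stage2_acc = s2,
                                baseline_acc = if (baseline) base_acc else NA_real_),
             confusion = conf)
}

#' Evaluate on an independent test set
#'
#' Fits the two-stage chain on all of `train` and scores `test`: stage-1
#' accuracy on all test rows, stage-2 accuracy on test rows with true top
#' label NS, combined with the test set's class fractions (or the configured
#' overrides).
#'
#' @param config A [pipeline_config()].
#' @param train,test [labeled_dataset()]s sharing the descriptor columns.
#' @param seed Root seed (default `config$eval$seed`).
#' @return An `evaluation_report` with protocol `"independent"`.
#' @export
evaluate_independent <- function(config, train, test, seed = NULL) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(test, "labeled_dataset"))
  config <- validate_config(config)
  seed <- seed %||% config$eval$seed
  if (!identical(colnames(train$descriptors), colnames(test$descriptors)))
    mt_validation_error("train and test descriptor columns differ")
  xj <- rbind(train$descriptors, test$descriptors)
  # prefixes keep row ids unique even when train and test overlap
  rownames(xj) <- c(paste0("train:", rownames(train$descriptors)),
                    paste0("test:", rownames(test$descriptors)))
  joint <- labeled_dataset(xj,
                           c(as.character(train$top_labels), as.character(test$top_labels)),
                           c(as.character(train$sub_labels), as.character(test$sub_labels)))
  res <- two_stage_split_eval(joint, seq_len(nrow(train$descriptors)),
                              nrow(train$descriptors) + seq_len(nrow(test$descriptors)),
                              config, derive_seed(seed, 3000L))
  fr <- resolve_fractions(config, test$top_labels)
  new_report(res$stage1_acc, res$stage2_acc, fr$ns, fr$sc,
             protocol = "independent",
             confusion = table(true = res$leaf_true, predicted = res$leaf_pred))
}

# Naive multiclass baseline on one split: one preprocessing chain (selection
# scored on the flattened leaf labels, stage-1 dimred settings) and a single
# MLP over the flat classes.
naive_split_eval <- function(data, train_idx, test_idx, config, seed) {
  leaf <- leaf_labels(data$top_labels, data$sub_labels)
  st <- stage_run(data$descriptors[train_idx, , drop = FALSE],
                  droplevels(leaf[train_idx]),
                  data$descriptors[test_idx, , drop = FALSE],
                  config, "stage1", seed)
  pred <- st$test_pred$labels
  list(stage = st, pred = pred,
       accuracy = mean(as.character(pred) == as.character(leaf[test_idx])))
}

#' Fit the naive multiclass baseline
#'
#' Flattens the two-level labels into leaf classes (`AD`, `SQ`, `SC`, plus
#' `NS` for NS rows without a known subtype) and fits a single classifier
#' over them with the same preprocessing chain as stage 1.
#'
#' @param train A [labeled_dataset()].
#' @param config A [pipeline_config()].
#' @param seed Root seed (default `config$seed`).
#' @return A list of class `naive_multiclass_model` with the fitted stage
#'   chain; predict with [predict_naive_multiclass()].
#' @export
fit_naive_multiclass <- function(train, config = pipeline_config(), seed = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  config <- validate_config(config)
  seed <- seed %||% config$seed
  leaf <- droplevels(leaf_labels(train$top_labels, train$sub_labels))
  if (nlevels(leaf) < 2L) mt_validation_error("need at least 2 leaf classes")
  st <- stage_run(train$descriptors, leaf, NULL, config, "stage1",
                  derive_seed(seed, 404L))
  structure(list(stage = st, classes = levels(leaf)),
            class = "naive_multiclass_model")
}

#' Predict with the naive multiclass baseline
#'
#' @param model A [fit_naive_multiclass()] model.
#' @param X Descriptor matrix.
#' @return As [mlp_predict()]: `labels` and `probabilities`.
#' @export
predict_naive_multiclass <- function(model, X) {
  stopifnot(inherits(model, "naive_multiclass_model"))
  stage_predict(model$stage, X)
}
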