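test_that("generator is deterministic with exact class counts", {
  spec <- synthetic_spec(seed = 5)
  g1 <- generate_hierarchical_dataset(spec)
  g2 <- generate_hierarchical_dataset(spec)
  expect_identical(g1, g2)

  d <- g1$dataset
  expect_equal(nrow(d$descriptors), 125)   # 44 + 46 + 35
  expect_equal(ncol(d$descriptors), 200)
  leaf <- table(leaf_labels(d$top_labels, d$sub_labels))
  expect_equal(as.vector(leaf[c("AD", "SQ", "SC")]), c(44L, 46L, 35L))
  expect_true(all(d$sub_labels[d$top_labels == "SC"] == "NONE"))
  expect_equal(g1$table$name, rownames(d$descriptors))

  g3 <- generate_hierarchical_dataset(synthetic_spec(seed = 6))
  expect_false(identical(g1$dataset$descriptors, g3$dataset$descriptors))
})

test_that("spec validation catches malformed worlds", {
  expect_error(synthetic_spec(n_per_leaf = c(AD = 3, SQ = 10, SC = 10)),
               "at least 4")
  expect_error(synthetic_spec(n_informative = 300, n_dims = 200),
               "n_informative")
  expect_error(synthetic_spec(n_per_leaf = c(AD = 10, SQ = 10)), "n_per_leaf")
})

test_that("p-values and fold changes respect the significance fraction", {
  g <- generate_hierarchical_dataset(synthetic_spec(seed = 7, sig_frac = 0.8))
  pass <- g$table$p_value <= 0.05 & g$table$fold_change >= 1.2
  expect_gt(mean(pass), 0.65)
  expect_lt(mean(pass), 0.95)
  g2 <- generate_hierarchical_dataset(synthetic_spec(seed = 7, sig_frac = 1))
  expect_true(all(g2$table$p_value <= 0.05 & g2$table$fold_change >= 1.2))
})

test_that("shells geometry defeats a linear classifier but not local structure", {
  d <- generate_hierarchical_dataset(synthetic_spec(seed = 42))$dataset
  x <- d$descriptors; y <- d$top_labels
  set.seed(1)
  folds <- sample(rep(1:5, length.out = nrow(x)))
  preds <- rep(NA_character_, nrow(x))
  for (f in 1:5) {
    tr <- folds != f
    fit <- glmnet::glmnet(x[tr, ], y[tr], family = "binomial", lambda = 0.01)
    preds[!tr] <- ifelse(predict(fit, x[!tr, ], type = "response") > 0.5,
                         "SC", "NS")
  }
  bal <- mean(c(mean(preds[y == "NS"] == "NS"), mean(preds[y == "SC"] == "SC")))
  expect_lte(bal, 0.7)   # concentric split is not linearly separable

  # the nonlinear pipeline's raw material: nearest neighbors share labels
  xn <- apply_normalization(x, fit_normalization(x))
  dm <- as.matrix(dist(xn)); diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)
  expect_gte(mean(y[nn] == y), 0.9)
})

test_that("noiseless linear world is perfectly recovered end to end", {
  spec <- synthetic_spec(n_per_leaf = c(AD = 8L, SQ = 8L, SC = 8L),
                         n_dims = 40L, n_informative = 20L,
                         top_geometry = "linear", noise_sd = 0, seed = 8)
  d <- generate_hierarchical_dataset(spec)$dataset
  rep <- suppressWarnings(
    cross_validate(d, k = 4, config = tiny_config(), seed = 21))
  expect_equal(rep$overall_acc, 1)
})

test_that("stage-2 accuracy rises with the sub-split separation", {
  cfg <- tiny_config()
  # linear top geometry so the sub-split is the dominant latent direction
  # and its recovery is a clean function of sub_separation
  mean_s2 <- vapply(c(0.5, 3, 6), function(sep) {
    mean(vapply(1:5, function(s) {
      d <- generate_hierarchical_dataset(
        small_spec(seed = 100 + s, sub_separation = sep,
                   top_geometry = "linear"))$dataset
      cross_validate(d, k = 4, config = cfg, seed = s)$stage2_acc
    }, 0))
  }, 0)
  expect_gte(mean_s2[2], mean_s2[1])
  expect_gte(mean_s2[3] + 0.02, mean_s2[2])  # tolerance for ceiling ties
  expect_gt(mean_s2[3], mean_s2[1])
})

test_that("the SMILES fixture is fixed and well-formed", {
  f <- fixture_smiles()
  expect_gte(length(f), 15)
  expect_true(all(nzchar(f)))
  expect_false(anyDuplicated(names(f)) > 0)
  expect_true(all(c("tryptophan", "methionine", "proline") %in% names(f)))
})
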