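# Shared fixtures: all built in code at test time, no files.

mt_verbose(FALSE)

# A 4-record table covering every leaf label.
tiny_table <- function() {
  metabolite_table(
    name = c("m1", "m2", "m3", "m4"),
    p_value = c(0.01, 0.02, 0.03, 0.04),
    fold_change = c(1.5, 1.6, 1.7, 1.8),
    label = c("AD", "SQ", "SC", "NS"),
    smiles = c("C", "CC", "CCO", "CCN")
  )
}

rand_table <- function(n, seed) {
  set.seed(seed)
  metabolite_table(
    name = sprintf("met%03d", seq_len(n)),
    p_value = round(runif(n), 6),
    fold_change = round(exp(rnorm(n, 0.2, 0.4)), 6),
    label = sample(c("AD", "SQ", "SC", "NS"), n, replace = TRUE),
    smiles = replicate(n, paste(sample(c("C", "N", "O", "(", ")", "=", "1"),
                                       sample(3:12, 1), replace = TRUE),
                                collapse = ""))
  )
}

rand_matrix <- function(n, m, seed) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("r%03d", seq_len(n)),
                         sprintf("c%03d", seq_len(m))))
}

# Small generator spec for unit tests (fast; the acceptance suite uses the
# full default spec).
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(n_per_leaf = c(AD = 10L, SQ = 10L, SC = 8L),
                 n_dims = 40L, n_informative = 20L, seed = seed, ...)
}

# Cheap pipeline config for unit tests: same structure as the default, small
# network and short embeddings so a CV run takes seconds.  Overrides are
# merged recursively.
tiny_config <- function(...) {
  base <- list(
    select = list(k = 30L),
    stage1 = list(tsne = list(n_iter = 300L)),
    stage2 = list(tsne = list(n_iter = 300L)),
    mlp = list(hidden_sizes = c(32L, 16L), epochs = 150L)
  )
  do.call(pipeline_config, utils::modifyList(base, list(...)))
}

# Two linearly separable 2-D Gaussian blobs.
blobs_2d <- function(n_per = 30L, sep = 6, seed = 42L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = sep), ncol = 2))
  colnames(x) <- c("f1", "f2")
  rownames(x) <- sprintf("s%03d", seq_len(2 * n_per))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per)))
}

# XOR-style blobs: not separable by a 1-unit network, easy for a wider one.
xor_blobs <- function(n_per = 20L, seed = 7L) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(6, 6), c(0, 6), c(6, 0))
  lab <- c("a", "a", "b", "b")
  x <- do.call(rbind, lapply(1:4, function(i)
    cbind(rnorm(n_per, centers[i, 1], 0.5), rnorm(n_per, centers[i, 2], 0.5))))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = factor(rep(lab, each = n_per)))
}
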