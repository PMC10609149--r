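# PCA ---------------------------------------------------------------------

test_that("PCA recovers collinear structure", {
  set.seed(1)
  t <- rnorm(30)
  x <- cbind(a = t, b = t)
  m <- pca_fit(x, 2)
  expect_equal(abs(m$components[1, ]), rep(1 / sqrt(2), 2), tolerance = 1e-8)
  expect_equal(m$eigenvalues[2], 0, tolerance = 1e-10)
  expect_gt(m$components[1, which.max(abs(m$components[1, ]))], 0)
})

test_that("full-rank PCA reconstructs the input", {
  x <- rand_matrix(20, 6, seed = 2)
  m <- pca_fit(x, 6)
  proj <- pca_transform(m, x)$coords
  back <- proj %*% m$components + matrix(m$mean, 20, 6, byrow = TRUE)
  expect_equal(unname(back), unname(x), tolerance = 1e-8)
})

test_that("PCA agrees with an SVD oracle", {
  for (s in 1:5) {
    x <- rand_matrix(50, 8, seed = 200 + s)
    m <- pca_fit(x, 8)
    sv <- svd(scale(x, center = TRUE, scale = FALSE))
    expect_equal(m$eigenvalues, sv$d^2 / (nrow(x) - 1), tolerance = 1e-8)
    for (i in 1:8) {
      v <- sv$v[, i]
      expect_equal(abs(sum(m$components[i, ] * v)), 1, tolerance = 1e-6)
    }
    expect_equal(unname(m$components %*% t(m$components)), diag(8),
                 tolerance = 1e-8)
  }
})

test_that("pca_transform centers and preserves variances", {
  x <- rand_matrix(40, 5, seed = 3)
  m <- pca_fit(x, 3)
  expect_equal(unname(pca_transform(m, m$mean)$coords), matrix(0, 1, 3),
               tolerance = 1e-10)
  proj <- pca_transform(m, x)$coords
  expect_equal(unname(apply(proj, 2, var)), m$eigenvalues, tolerance = 1e-8)
  expect_error(pca_transform(m, x[, 1:3]), "columns")
  expect_error(pca_fit(x, 6), "n_components")
})

# t-SNE similarity laws ----------------------------------------------------

test_that("conditional probabilities are row-normalized with zero diagonal", {
  x <- rand_matrix(20, 5, seed = 4)
  p <- tsne_conditional_probs(x, perplexity = 6)
  expect_equal(unname(diag(p)), rep(0, 20))
  expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-10)
})

test_that("equilateral triangle gives uniform conditionals", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  rownames(tri) <- c("a", "b", "c"); colnames(tri) <- c("x", "y")
  p <- tsne_conditional_probs(tri, perplexity = 2)
  off <- p[row(p) != col(p)]
  expect_equal(off, rep(0.5, 6), tolerance = 1e-8)
})

test_that("calibrated rows hit the target perplexity", {
  x <- rand_matrix(20, 4, seed = 5)
  target <- 7
  p <- tsne_conditional_probs(x, target)
  for (i in 1:20) {
    pr <- p[i, -i]
    h <- -sum(pr[pr > 0] * log2(pr[pr > 0]))
    expect_equal(2^h, target, tolerance = 1e-4)
  }
})

test_that("symmetrized similarities are symmetric with unit mass", {
  x <- rand_matrix(15, 4, seed = 6)
  p <- tsne_conditional_probs(x, 5)
  s <- tsne_symmetrize(p)
  expect_equal(s, t(s))
  expect_equal(sum(s), 1, tolerance = 1e-10)
  expect_equal(unname(diag(s)), rep(0, 15))
  # symmetric P is a fixed point up to the 1/N scale
  ps <- (p + t(p)) / 2
  expect_equal(tsne_symmetrize(ps), ps / 15, tolerance = 1e-12)
})

test_that("low-dimensional affinities follow the Student-t kernel", {
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  q2 <- tsne_low_dim_affinities(two)
  expect_equal(unname(q2), matrix(c(0, 0.5, 0.5, 0), 2, 2))

  y <- rand_matrix(15, 2, seed = 7)
  q <- tsne_low_dim_affinities(y)
  # brute-force double loop
  w <- matrix(0, 15, 15)
  for (i in 1:15) for (j in 1:15) if (i != j)
    w[i, j] <- 1 / (1 + sum((y[i, ] - y[j, ])^2))
  expect_equal(unname(q), w / sum(w), tolerance = 1e-12)
  expect_equal(sum(q), 1, tolerance = 1e-10)

  # coincident points carry the maximal kernel value before normalization
  y2 <- y; y2[2, ] <- y2[1, ]
  q3 <- tsne_low_dim_affinities(y2)
  expect_equal(which(q3 == max(q3), arr.ind = TRUE)[1, ], c(row = 2, col = 1))
})

test_that("KL divergence satisfies its identities", {
  y <- rand_matrix(12, 2, seed = 8)
  q <- tsne_low_dim_affinities(y)
  expect_equal(kl_divergence(q, q), 0)

  x <- rand_matrix(12, 5, seed = 9)
  s <- tsne_symmetrize(tsne_conditional_probs(x, 4))
  kl <- kl_divergence(s, q)
  expect_gte(kl, 0)
  # term-by-term oracle
  terms <- 0
  for (i in 1:12) for (j in 1:12)
    if (i != j && s[i, j] > 0) terms <- terms + s[i, j] * log(s[i, j] / q[i, j])
  expect_equal(kl, terms, tolerance = 1e-12)

  qz <- q; qz[1, 2] <- 0
  expect_warning(kl_divergence(s, qz), "flooring")
})

# t-SNE embedding ----------------------------------------------------------

test_that("embedding is deterministic and recovers separated clusters", {
  set.seed(10)
  x <- rbind(matrix(rnorm(10 * 20), 10, 20),
             matrix(rnorm(10 * 20, mean = 8), 10, 20))
  rownames(x) <- sprintf("p%02d", 1:20); colnames(x) <- sprintf("d%02d", 1:20)
  cfg <- tsne_config(out_dim = 2, perplexity = 5, n_iter = 500, seed = 33)
  e1 <- tsne_embed(x, cfg)
  e2 <- tsne_embed(x, cfg)
  expect_identical(e1$coords, e2$coords)
  expect_true(all(is.finite(e1$coords)))
  expect_gte(e1$final_kl, 0)

  # nearest-centroid recovery of cluster identity is perfect
  cl <- rep(1:2, each = 10)
  cents <- rbind(colMeans(e1$coords[1:10, ]), colMeans(e1$coords[11:20, ]))
  assign <- apply(e1$coords, 1, function(p)
    which.min(colSums((t(cents) - p)^2)))
  expect_equal(unname(assign), cl)

  # KL at the end does not exceed KL just after early exaggeration
  expect_lte(rev(e1$kl_trace)[1], e1$kl_trace[["50"]])
})

test_that("knn mapping places new points near their neighbors", {
  set.seed(11)
  x <- rbind(matrix(rnorm(10 * 5), 10, 5), matrix(rnorm(10 * 5, 6), 10, 5))
  e <- tsne_embed(x, tsne_config(out_dim = 2, perplexity = 5,
                                 n_iter = 300, seed = 1))
  new <- rbind(rnorm(5), rnorm(5, 6))
  mapped <- tsne_knn_map(x, e$coords, new, kappa = 5)
  c1 <- colMeans(e$coords[1:10, ]); c2 <- colMeans(e$coords[11:20, ])
  expect_lt(sum((mapped[1, ] - c1)^2), sum((mapped[1, ] - c2)^2))
  expect_lt(sum((mapped[2, ] - c2)^2), sum((mapped[2, ] - c1)^2))
})
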