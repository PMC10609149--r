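# Dimensionality reduction: PCA via covariance eigendecomposition, and t-SNE
# written from first principles (perplexity-calibrated Gaussian conditionals,
# symmetrized similarities, Student-t low-dimensional affinities, KL-descent
# by gradient descent with momentum and early exaggeration).

#' Fit PCA by eigendecomposition of the sample covariance
#'
#' Centers the data, eigendecomposes the sample covariance (divisor `N - 1`,
#' so eigenvalues equal the variances of the projected training data) and
#' keeps the leading `n_components` eigenvectors.  Sign convention: each
#' component's largest-magnitude entry is positive, making fits
#' deterministic.
#'
#' @param matrix Numeric matrix (N x m), N >= 2.
#' @param n_components Number of components, at most `min(N, m)` (default 3).
#' @return A list of class `pca_model` with `mean`, `components` (rows are
#'   orthonormal eigenvectors) and `eigenvalues` (descending).
#' @export
pca_fit <- function(matrix, n_components = 3L) {
  check_matrix(matrix, "matrix")
  if (nrow(matrix) < 2L) mt_validation_error("PCA needs at least 2 rows")
  check_number(n_components, "pca.n_components", lower = 1, integer = TRUE)
  if (n_components > min(dim(matrix)))
    mt_validation_error("pca.n_components (", n_components,
                        ") exceeds min(N, m) = ", min(dim(matrix)))
  mu <- colMeans(matrix)
  xc <- sweep(matrix, 2L, mu, "-")
  cov_x <- crossprod(xc) / (nrow(matrix) - 1)
  eig <- eigen(cov_x, symmetric = TRUE)
  comp <- t(eig$vectors[, seq_len(n_components), drop = FALSE])
  for (i in seq_len(nrow(comp))) {            # deterministic sign
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(
    mean = mu,
    components = comp,
    eigenvalues = pmax(eig$values[seq_len(n_components)], 0)
  ), class = "pca_model")
}

#' Project data onto fitted principal components
#'
#' @param model A [pca_fit()] model.
#' @param matrix Numeric matrix with the same columns as the training data.
#' @return An `embedding` list: `coords` (N x n_components), `method`
#'   (`"pca"`), `final_kl` (0 for PCA).
#' @export
pca_transform <- function(model, matrix) {
  stopifnot(inherits(model, "pca_model"))
  if (is.vector(matrix)) matrix <- matrix(matrix, nrow = 1L)
  if (ncol(matrix) != length(model$mean))
    mt_validation_error("matrix has ", ncol(matrix), " columns; model expects ",
                        length(model$mean))
  coords <- sweep(matrix, 2L, model$mean, "-") %*% t(model$components)
  structure(list(coords = coords, final_kl = 0, method = "pca"),
            class = "embedding")
}

#' t-SNE configuration
#'
#' @param out_dim Embedding dimension, 2 or 3 (default 3).
#' @param perplexity Target perplexity (effective neighbor count `2^H` of
#'   each point's conditional distribution); must be below the number of
#'   points.  `NULL` (default) resolves at fit time to `min(30, (N - 1) / 3)`.
#' @param n_iter Gradient-descent iterations (default 1000).
#' @param learning_rate_embed Step size on the embedding coordinates
#'   (default 200).
#' @param momentum Initial momentum (default 0.5; raised to 0.8 at
#'   iteration 250 as in the original optimizer).
#' @param seed Integer seed for the Gaussian initialization.
#' @return A list of class `tsne_config`.
#' @export
tsne_config <- function(out_dim = 3L, perplexity = NULL, n_iter = 1000L,
                        learning_rate_embed = 200, momentum = 0.5, seed = 1L) {
  check_number(out_dim, "tsne.out_dim", lower = 2, upper = 3, integer = TRUE)
  if (!is.null(perplexity))
    check_number(perplexity, "tsne.perplexity", lower = 0, open_lower = TRUE)
  check_number(n_iter, "tsne.n_iter", lower = 1, integer = TRUE)
  check_number(learning_rate_embed, "tsne.learning_rate_embed", lower = 0, open_lower = TRUE)
  check_number(momentum, "tsne.momentum", lower = 0, upper = 1, open_upper = TRUE)
  check_number(seed, "tsne.seed", integer = TRUE)
  structure(list(out_dim = as.integer(out_dim), perplexity = perplexity,
                 n_iter = as.integer(n_iter),
                 learning_rate_embed = learning_rate_embed,
                 momentum = momentum, seed = as.integer(seed)),
            class = "tsne_config")
}

default_perplexity <- function(n) min(30, (n - 1) / 3)

squared_distances <- function(x) {
  s <- rowSums(x * x)
  d <- outer(s, s, "+") - 2 * tcrossprod(x)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Perplexity-calibrated conditional similarities
#'
#' For each point i, the Gaussian bandwidth `sigma_i` is found by binary
#' search (at most 64 iterations) so that the perplexity `2^H(Pr(.|i))` of
#' the conditional distribution over neighbors matches the target within
#' 1e-5.  `Pr(i|i) = 0` and every row sums to 1.
#'
#' @param matrix Numeric matrix (N x k), N >= 3.
#' @param perplexity Target perplexity, below N.
#' @return N x N matrix of conditional probabilities `P[i, j] = Pr(j | i)`.
#' @export
tsne_conditional_probs <- function(matrix, perplexity) {
  check_matrix(matrix, "matrix")
  n <- nrow(matrix)
  if (n < 3L) mt_validation_error("t-SNE needs at least 3 points")
  check_number(perplexity, "tsne.perplexity", lower = 0, upper = n,
               open_lower = TRUE, open_upper = TRUE)
  d2 <- squared_distances(matrix)
  target <- log2(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1        # beta = 1 / (2 sigma_i^2)
    lo <- 0; hi <- Inf
    for (iter in seq_len(64L)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { hi <- beta; beta <- beta / 2; next }
      pr <- w / sw
      h <- -sum(pr[pr > 0] * log2(pr[pr > 0]))   # row entropy, bits
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2 }
      else            { hi <- beta; beta <- (lo + hi) / 2 }
    }
    if (abs(h - target) >= 1e-5)
      warning("perplexity calibration did not converge for point ", i,
              " (entropy ", signif(h, 6), ", target ", signif(target, 6), ")")
    p[i, -i] <- pr
  }
  dimnames(p) <- list(rownames(matrix), rownames(matrix))
  p
}

#' Symmetrized joint similarities
#'
#' `S[i, j] = (Pr(i|j) + Pr(j|i)) / (2N)`: symmetric, zero diagonal, total
#' mass 1 when every row of `P` sums to 1.
#'
#' @param P Square conditional-probability matrix with unit row sums.
#' @return Symmetric joint similarity matrix `S`.
#' @export
tsne_symmetrize <- function(P) {
  check_matrix(P, "P")
  if (nrow(P) != ncol(P)) mt_validation_error("P must be square")
  s <- (P + t(P)) / (2 * nrow(P))
  diag(s) <- 0
  s
}

#' Low-dimensional Student-t affinities
#'
#' `Q[i, j]` is the normalized heavy-tailed kernel
#' `(1 + ||y_i - y_j||^2)^-1 / sum_{k != l} (1 + ||y_k - y_l||^2)^-1`:
#' symmetric, non-negative, zero diagonal, total mass 1.
#'
#' @param coords Embedding coordinates (N x d), N >= 2.
#' @return The Q matrix.
#' @export
tsne_low_dim_affinities <- function(coords) {
  check_matrix(coords, "coords")
  if (nrow(coords) < 2L) mt_validation_error("need at least 2 points")
  w <- 1 / (1 + squared_distances(coords))
  diag(w) <- 0
  w / sum(w)
}

#' Kullback-Leibler divergence between joint similarity matrices
#'
#' `KL(S || Q) = sum_{i != j} S[i,j] log(S[i,j] / Q[i,j])` with
#' `0 log(0/q) = 0`.  Where `Q` is zero but `S` is positive, `Q` is floored
#' at 1e-12 and a warning is logged.
#'
#' @param S,Q Same-shape joint matrices with entries in `[0, 1]`.
#' @return The (non-negative) divergence, in nats.
#' @export
kl_divergence <- function(S, Q) {
  check_matrix(S, "S"); check_matrix(Q, "Q")
  if (!identical(dim(S), dim(Q))) mt_validation_error("S and Q must have the same shape")
  pos <- S > 0
  qq <- Q[pos]
  if (any(qq <= 0)) {
    warning("Q has zero entries where S > 0; flooring Q at 1e-12")
    qq <- pmax(qq, 1e-12)
  }
  sum(S[pos] * log(S[pos] / qq))
}

#' Embed data with t-SNE
#'
#' Computes perplexity-calibrated conditionals, symmetrizes them, and runs
#' gradient descent on the embedding coordinates against the KL divergence,
#' with momentum (0.5, raised to 0.8 at iteration 250), early exaggeration
#' (similarities scaled by 4 for the first 50 iterations) and a seeded
#' Gaussian initialization (sd 1e-2).  Deterministic given the seed.
#'
#' @param matrix Numeric matrix (N x k) of input points.
#' @param config A [tsne_config()].
#' @return An `embedding` list: `coords` (N x out_dim), `final_kl` (the KL
#'   divergence at the final iteration, against the unexaggerated
#'   similarities), `method` (`"tsne"`), and `kl_trace` (KL recorded every
#'   50 iterations).
#' @export
tsne_embed <- function(matrix, config = tsne_config()) {
  check_matrix(matrix, "matrix")
  stopifnot(inherits(config, "tsne_config"))
  n <- nrow(matrix)
  perp <- config$perplexity %||% default_perplexity(n)
  p <- tsne_conditional_probs(matrix, perp)
  s <- tsne_symmetrize(p)

  d <- config$out_dim
  y0 <- with_seed(config$seed,
                  matrix(stats::rnorm(n * d, sd = 1e-2), n, d))
  # momentum + adaptive gains + early exaggeration (x4, 50 iterations),
  # momentum raised to 0.8 at iteration 250; inner loop in C++ (src/tsne.cpp)
  desc <- cpp_tsne_descent(s, y0, config$n_iter,
                           config$learning_rate_embed, config$momentum,
                           4, 50L, 250L)
  y <- desc$coords
  kl_trace <- stats::setNames(desc$kl_trace, desc$trace_iter)
  final_q <- tsne_low_dim_affinities(y)
  rownames(y) <- rownames(matrix)
  structure(list(coords = y,
                 final_kl = kl_divergence(s, final_q),
                 method = "tsne",
                 kl_trace = kl_trace),
            class = "embedding")
}

# Map out-of-sample points into a fitted t-SNE embedding as the
# inverse-distance-weighted mean of the embeddings of their kappa nearest
# training points (distances measured in the selected-feature space).
tsne_knn_map <- function(train_x, train_coords, new_x, kappa = 5L) {
  kappa <- min(kappa, nrow(train_x))
  out <- matrix(0, nrow(new_x), ncol(train_coords))
  for (i in seq_len(nrow(new_x))) {
    d <- sqrt(colSums((t(train_x) - new_x[i, ])^2))
    nn <- order(d)[seq_len(kappa)]
    w <- 1 / pmax(d[nn], 1e-12)
    out[i, ] <- colSums(train_coords[nn, , drop = FALSE] * w) / sum(w)
  }
  rownames(out) <- rownames(new_x)
  out
}
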