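# Seeded generator of hierarchical labeled datasets: a two-level cluster
# structure (NS/SC top split, AD/SQ sub-split within NS) planted in a
# high-dimensional descriptor space, plus per-record p-values/fold changes so
# the significance filter has something to act on.

#' Synthetic dataset specification
#'
#' The generator plants a 3-dimensional latent signal -- a 2-D top-split
#' geometry (NS vs SC) and a 1-D AD-vs-SQ shift within NS -- into
#' `n_informative` descriptor columns through a fixed random projection; the
#' remaining columns are pure noise.  With `top_geometry = "shells"` the top
#' split is concentric (SC a Gaussian disk at the origin, NS a ring around
#' it), which is not linearly separable; `"linear"` uses a plain mean shift.
#' Leaf counts default to 44 AD, 46 SQ, 35 SC (125 metabolites).
#'
#' @param n_per_leaf Named counts for leaves `AD`, `SQ`, `SC` (each >= 4).
#' @param n_dims Total descriptor count (default 200; use 1083 for the
#'   paper-scale feature path).
#' @param n_informative Number of signal-carrying descriptors (default 80).
#' @param top_geometry `"shells"` (default; nonlinear top split) or
#'   `"linear"`.
#' @param sub_separation Latent mean shift between AD and SQ, in noise-sd
#'   units (default 6).
#' @param noise_sd Standard deviation of descriptor noise (default 1).
#' @param sig_frac Fraction of records drawn to pass the p/FC filter
#'   (default 0.8).
#' @param p_value_model,fc_model Uniform p-value ranges and log-normal fold
#'   change parameters for significant vs null records; see defaults.
#' @param seed Integer seed; the same spec and seed give an identical dataset.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_leaf = c(AD = 44L, SQ = 46L, SC = 35L),
                           n_dims = 200L, n_informative = 80L,
                           top_geometry = c("shells", "linear"),
                           sub_separation = 6, noise_sd = 1,
                           sig_frac = 0.8,
                           p_value_model = list(sig = c(0.001, 0.05),
                                                null = c(0.051, 1)),
                           fc_model = list(sig = c(meanlog = log(1.8), sdlog = 0.25),
                                           null = c(meanlog = log(1.05), sdlog = 0.15)),
                           seed = 1L) {
  top_geometry <- match.arg(top_geometry)
  if (!all(c("AD", "SQ", "SC") %in% names(n_per_leaf)))
    mt_validation_error("n_per_leaf must name AD, SQ and SC")
  n_per_leaf <- vapply(c("AD", "SQ", "SC"), function(k) as.integer(n_per_leaf[[k]]), 0L)
  if (any(n_per_leaf < 4L))
    mt_validation_error("each leaf needs at least 4 samples")
  check_number(n_dims, "n_dims", lower = 3, integer = TRUE)
  check_number(n_informative, "n_informative", lower = 3, integer = TRUE)
  if (n_informative > n_dims)
    mt_validation_error("n_informative must not exceed n_dims")
  check_number(sub_separation, "sub_separation", lower = 0, open_lower = TRUE)
  # noise_sd = 0 is allowed: the degenerate noiseless world, used to check
  # that the full pipeline recovers a perfectly separable construction
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sig_frac, "sig_frac", lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)
  structure(list(n_per_leaf = n_per_leaf, n_dims = as.integer(n_dims),
                 n_informative = as.integer(n_informative),
                 top_geometry = top_geometry,
                 sub_separation = sub_separation, noise_sd = noise_sd,
                 sig_frac = sig_frac, p_value_model = p_value_model,
                 fc_model = fc_model, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Construction constants of the latent geometry (absolute units; the default
# noise_sd of 1 makes them multiples of the noise scale): see the methods
# vignette for how they were fixed.
.shell_inner_sd <- 1.5   # SC disk spread
.shell_outer_r  <- 8     # NS ring radius
.linear_shift   <- 6     # NS vs SC mean shift under "linear"
.proj_row_norm  <- 3     # informative-descriptor loading magnitude

#' Generate a hierarchical synthetic dataset
#'
#' Draws the latent two-level structure described in [synthetic_spec()],
#' projects it into the informative descriptors, adds Gaussian noise
#' everywhere, applies a random per-column affine rescaling (descriptor
#' heterogeneity; min-max normalization removes it again), and attaches
#' p-values/fold changes such that about `sig_frac` of records pass the
#' standard filter.  Fully deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (a [metabolite_table()]) and `dataset`
#'   (a [labeled_dataset()] over all generated rows).
#' @export
generate_hierarchical_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    counts <- spec$n_per_leaf
    n <- sum(counts)
    leaf <- rep(c("AD", "SQ", "SC"), counts)
    top <- ifelse(leaf == "SC", "SC", "NS")
    sub <- ifelse(leaf == "SC", "NONE", leaf)
    sdn <- spec$noise_sd

    # latent top-split coordinates (2-D); separations are absolute so that
    # noise_sd scales only the noise, down to the noiseless degenerate case
    z <- matrix(0, n, 2L)
    is_sc <- top == "SC"
    if (spec$top_geometry == "shells") {
      z[is_sc, ] <- matrix(stats::rnorm(2L * sum(is_sc), sd = .shell_inner_sd),
                           ncol = 2L)
      theta <- stats::runif(sum(!is_sc), 0, 2 * pi)
      r <- .shell_outer_r + stats::rnorm(sum(!is_sc), sd = sdn)
      z[!is_sc, ] <- cbind(r * cos(theta), r * sin(theta))
    } else {
      z[, 1L] <- ifelse(is_sc, -.linear_shift / 2, .linear_shift / 2)
      z <- z + matrix(stats::rnorm(2L * n, sd = sdn), ncol = 2L)
    }
    # latent sub-split coordinate (1-D, meaningful only within NS)
    w <- numeric(n)
    w[leaf == "AD"] <- +spec$sub_separation / 2
    w[leaf == "SQ"] <- -spec$sub_separation / 2
    latent <- cbind(z, w)

    # project into the informative descriptors; unit-direction rows scaled to
    # a fixed loading norm so the signal dominates the per-column noise
    a <- matrix(stats::rnorm(spec$n_informative * 3L), spec$n_informative, 3L)
    a <- a / sqrt(rowSums(a^2)) * .proj_row_norm
    x <- matrix(stats::rnorm(n * spec$n_dims, sd = sdn), n, spec$n_dims)
    x[, seq_len(spec$n_informative)] <-
      x[, seq_len(spec$n_informative), drop = FALSE] + latent %*% t(a)

    # descriptor heterogeneity: random per-column affine map
    scales <- stats::runif(spec$n_dims, 0.5, 2)
    offsets <- stats::rnorm(spec$n_dims, 0, 3)
    x <- sweep(sweep(x, 2L, scales, "*"), 2L, offsets, "+")

    names_ <- sprintf("met_%03d", seq_len(n))
    dimnames(x) <- list(names_, sprintf("D%04d", seq_len(spec$n_dims)))

    # p-values / fold changes: `sig` records pass the filter, `null` fail
    sig <- stats::runif(n) < spec$sig_frac
    pv <- ifelse(sig,
                 stats::runif(n, spec$p_value_model$sig[1], spec$p_value_model$sig[2]),
                 stats::runif(n, spec$p_value_model$null[1], spec$p_value_model$null[2]))
    # null records already fail via p > 0.05, so only significant records'
    # FC needs the floor at the filter threshold
    fc_sig <- pmax(stats::rlnorm(n, spec$fc_model$sig[["meanlog"]],
                                 spec$fc_model$sig[["sdlog"]]), 1.2)
    fc_null <- stats::rlnorm(n, spec$fc_model$null[["meanlog"]],
                             spec$fc_model$null[["sdlog"]])
    fc <- ifelse(sig, fc_sig, fc_null)

    table <- metabolite_table(names_, pv, fc, leaf)
    list(table = table,
         dataset = labeled_dataset(x, top, sub))
  })
}

#' Packaged metabolite SMILES fixture
#'
#' A fixed list of real metabolite SMILES (amino-acid biomarkers such as
#' tryptophan, methionine and proline, glutathione, pantothenate, and common
#' fatty acids) for exercising the descriptor adapter without an external
#' chemistry engine.
#'
#' @return Named character vector (name -> SMILES), length >= 15.
#' @export
fixture_smiles <- function() {
  c(
    tryptophan    = "C1=CC=C2C(=C1)C(=CN2)CC(C(=O)O)N",
    methionine    = "CSCCC(C(=O)O)N",
    proline       = "C1CC(NC1)C(=O)O",
    alanine       = "CC(C(=O)O)N",
    aspartate     = "C(C(C(=O)O)N)C(=O)O",
    glutamate     = "C(CC(=O)O)C(C(=O)O)N",
    glutamine     = "C(CC(=O)N)C(C(=O)O)N",
    glycine       = "C(C(=O)O)N",
    serine        = "C(C(C(=O)O)N)O",
    threonine     = "CC(C(C(=O)O)N)O",
    valine        = "CC(C)C(C(=O)O)N",
    leucine       = "CC(C)CC(C(=O)O)N",
    isoleucine    = "CCC(C)C(C(=O)O)N",
    phenylalanine = "C1=CC=C(C=C1)CC(C(=O)O)N",
    tyrosine      = "C1=CC(=CC=C1CC(C(=O)O)N)O",
    cysteine      = "C(C(C(=O)O)N)S",
    glutathione   = "C(CC(=O)NC(CS)C(=O)NCC(=O)O)C(C(=O)O)N",
    pantothenate  = "CC(C)(CO)C(C(=O)NCCC(=O)O)O",
    palmitate     = "CCCCCCCCCCCCCCCC(=O)O",
    stearate      = "CCCCCCCCCCCCCCCCCC(=O)O",
    oleate        = "CCCCCCCCC=CCCCCCCCC(=O)O",
    linoleate     = "CCCCCC=CCC=CCCCCCCCC(=O)O"
  )
}
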