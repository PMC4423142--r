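#' Simulate a sparse-signal QSAR regression dataset
#'
#' Generates a descriptor matrix with optional highly correlated column
#' blocks (to exercise the collinearity filter) and an activity vector that
#' is an exact sparse linear function of a few "true" descriptors plus
#' Gaussian noise. The truth (support, coefficients, noise sd) is recorded
#' so selection methods can be scored against it.
#'
#' Columns are standard normal. Each collinear block of `block_size`
#' decoy columns shares a common factor so that within-block correlations
#' are `block_rho`; true-signal columns are never placed in blocks, keeping
#' the ground truth identifiable. The five default true columns carry the
#' descriptor names of the final published models so that reports read like
#' real model tables.
#'
#' @param n compounds (default 30).
#' @param p descriptors (default 291, the size of a typical post-filter
#'   pool).
#' @param k_true number of informative descriptors (default 5).
#' @param beta_range absolute-coefficient range for the truth; signs
#'   alternate (default `c(1, 3)`).
#' @param noise_sd residual standard deviation; when `NULL` it is set from
#'   `snr` as `sd(signal)/snr`.
#' @param snr signal-to-noise ratio used when `noise_sd` is `NULL`
#'   (default 10).
#' @param n_collinear_blocks number of correlated decoy blocks (default 5).
#' @param block_size columns per block (default 3).
#' @param block_rho within-block correlation (default 0.95).
#' @param intercept intercept of the true model (default 6, a plausible
#'   pIC50 scale).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_bundle`: `X`, `y`, `support`,
#'   `beta` (named), `intercept`, `noise_sd`, `seed`, `blocks`.
#' @export
make_regression_dataset <- function(n = 30L, p = 291L, k_true = 5L,
                                    beta_range = c(1, 3), noise_sd = NULL,
                                    snr = 10, n_collinear_blocks = 5L,
                                    block_size = 3L, block_rho = 0.95,
                                    intercept = 6, seed = 1L) {
  stopifnot(k_true <= p, block_rho >= 0, block_rho < 1,
            k_true + n_collinear_blocks * block_size <= p)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  true_names <- c("IC1", "Mor24m", "Mor15e", "RDF115m", "SP20",
                  sprintf("T%02d", seq_len(max(0L, k_true - 5L))))[seq_len(k_true)]
  cn <- c(true_names, sprintf("D%03d", seq_len(p - k_true)))
  colnames(X) <- cn
  blocks <- list()
  col0 <- k_true
  for (b in seq_len(n_collinear_blocks)) {
    idx <- col0 + seq_len(block_size)
    z <- stats::rnorm(n)
    X[, idx] <- sqrt(block_rho) * z +
      sqrt(1 - block_rho) * matrix(stats::rnorm(n * block_size), n)
    blocks[[b]] <- cn[idx]
    col0 <- col0 + block_size
  }
  sgn <- rep_len(c(1, -1), k_true)
  beta <- sgn * stats::runif(k_true, beta_range[1L], beta_range[2L])
  names(beta) <- true_names
  signal <- drop(X[, true_names, drop = FALSE] %*% beta)
  if (is.null(noise_sd)) noise_sd <- stats::sd(signal) / snr
  y <- intercept + signal + stats::rnorm(n, sd = noise_sd)
  rownames(X) <- sprintf("cmp%02d", seq_len(n))
  structure(list(X = X, y = y, support = true_names, beta = beta,
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed), blocks = blocks),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>", nrow(x$X), "x", ncol(x$X),
      "descriptors;", length(x$support), "true:",
      paste(x$support, collapse = ", "), "\n")
  cat("  noise sd:", signif(x$noise_sd, 3), " seed:", x$seed, "\n")
  invisible(x)
}

#' Random pseudo-molecule for descriptor unit tests
#'
#' Uniform random coordinates in a cubic box with a random spanning tree as
#' the bond graph, so every topological lag up to the tree diameter exists
#' and the graph is always connected.
#'
#' @param n_atoms number of atoms (>= 2).
#' @param elements element alphabet sampled uniformly (default C/N/O/H).
#' @param box box edge length, Angstrom (default 8).
#' @param seed integer RNG seed.
#' @return a [molecule].
#' @export
make_point_cloud_molecule <- function(n_atoms, elements = c("C", "N", "O", "H"),
                                      box = 8, seed = 1L) {
  stopifnot(n_atoms >= 2L)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  coords <- matrix(stats::runif(3L * n_atoms, 0, box), n_atoms, 3L)
  el <- sample(elements, n_atoms, replace = TRUE)
  parents <- if (n_atoms > 2L)
    vapply(2:n_atoms, function(i) sample.int(i - 1L, 1L), 1L) else 1L
  bonds <- cbind(i = parents, j = 2:n_atoms, order = 1L)
  molecule(sprintf("cloud%d_seed%d", n_atoms, seed), el, coords, bonds)
}

#' Canonical synthetic QSAR bundle with a calibration/validation split
#'
#' The default end-to-end fixture: a 30-compound x 291-descriptor bundle
#' with a 5-descriptor sparse truth at signal-to-noise ratio 10, mirroring
#' the dimensions of the real modelling problem (30 compounds, a
#' post-filter pool of 291, 24/6 calibration/validation).
#'
#' @param seed integer RNG seed.
#' @return list with `bundle` (a [make_regression_dataset()] result) and
#'   `split` (a [split_calibration_validation()] result with 24/6 rows).
#' @export
make_qsar_bundle <- function(seed = 1L) {
  bundle <- make_regression_dataset(seed = seed)
  split <- split_calibration_validation(bundle$X, bundle$y,
                                        validation_fraction = 0.2,
                                        seed = seed)
  list(bundle = bundle, split = split)
}
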