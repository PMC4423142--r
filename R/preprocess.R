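#' Remove constant and near-constant descriptor columns
#'
#' A column is dropped when (a) its standard deviation over non-missing
#' values is below `min_sd`, or (b) its most frequent value covers more
#' than `1 - min_unique_fraction` of the rows, or (c) it is entirely
#' missing. Undefined descriptor values (`NA`) count as a "value" for the
#' frequency rule, so columns that are mostly undefined are removed too.
#'
#' @param X numeric descriptor matrix (rows = compounds).
#' @param min_unique_fraction frequency threshold; default 0.1 means a
#'   column whose modal value covers > 90% of rows is dropped.
#' @param min_sd absolute standard-deviation floor.
#' @return the filtered matrix, with attribute `"removed"` listing the
#'   dropped column names.
#' @export
drop_near_constant <- function(X, min_unique_fraction = 0.1, min_sd = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  bad <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (all(is.na(x))) return(TRUE)
    if (stats::sd(x, na.rm = TRUE) < min_sd) return(TRUE)
    top <- max(table(x, useNA = "ifany"))
    top > (1 - min_unique_fraction) * n
  }, TRUE)
  if (all(bad)) stop("all columns removed as (near-)constant")
  out <- X[, !bad, drop = FALSE]
  attr(out, "removed") <- colnames(X)[bad]
  out
}

#' Remove collinear descriptors, keeping the more activity-correlated one
#'
#' Scans all column pairs with `|Pearson r| > r_cut` in decreasing `|r|`;
#' within each pair, the member with the lower `|cor(column, y)|` is
#' dropped (ties keep the earlier column, so the result is deterministic).
#' After the scan no surviving pair exceeds the cutoff.
#'
#' @param X numeric descriptor matrix.
#' @param y activity vector aligned with the rows of `X`.
#' @param r_cut collinearity cutoff on `|r|` (default 0.9).
#' @return filtered matrix with attribute `"removed"`.
#' @export
collinearity_filter <- function(X, y, r_cut = 0.9) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  p <- ncol(X)
  if (p < 2L) return(structure(X, removed = character()))
  R <- suppressWarnings(stats::cor(X))
  R[is.na(R)] <- 0
  ry <- abs(suppressWarnings(stats::cor(X, y)))
  ry[is.na(ry)] <- 0
  pairs <- which(abs(R) > r_cut & upper.tri(R), arr.ind = TRUE)
  keep <- rep(TRUE, p)
  if (nrow(pairs)) {
    ord <- order(abs(R[pairs]), decreasing = TRUE)
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (!keep[i] || !keep[j]) next
      # tie on |cor with y| keeps the earlier (lower-index) column
      drop <- if (ry[i] >= ry[j]) j else i
      keep[drop] <- FALSE
    }
  }
  out <- X[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(X)[!keep]
  out
}

#' Split compounds into calibration and validation sets
#'
#' Uniform random split without replacement, reproducible under `seed`.
#' The validation set holds `round(validation_fraction * n)` compounds
#' (30 compounds at the default 0.2 give 6 validation / 24 calibration).
#' `method = "systematic"` instead takes every k-th compound of the
#' activity-sorted order, for reproducibility studies.
#'
#' @param X descriptor matrix (only row count/names used).
#' @param y activity vector (used by the systematic mode).
#' @param validation_fraction fraction held out, in (0, 1).
#' @param seed integer RNG seed.
#' @param method `"random"` (default) or `"systematic"`.
#' @return object of class `qsar_split`: list with `calibration` and
#'   `validation` row indices, plus `seed`.
#' @export
split_calibration_validation <- function(X, y = NULL,
                                         validation_fraction = 0.2,
                                         seed = 1L,
                                         method = c("random", "systematic")) {
  method <- match.arg(method)
  stopifnot(validation_fraction > 0, validation_fraction < 1)
  n <- nrow(as.matrix(X))
  n_val <- round(validation_fraction * n)
  if (n - n_val < 1L || n_val < 1L)
    stop("validation fraction ", validation_fraction,
         " leaves an empty calibration or validation set at n = ", n)
  if (method == "random") {
    val <- local({
      old <- .Random.seed_get()
      on.exit(.Random.seed_set(old))
      set.seed(seed)
      sort(sample.int(n, n_val))
    })
  } else {
    ord <- order(y)
    val <- sort(ord[round(seq(1L, n, length.out = n_val))])
  }
  structure(list(calibration = setdiff(seq_len(n), val), validation = val,
                 seed = as.integer(seed)),
            class = "qsar_split")
}

#' @export
print.qsar_split <- function(x, ...) {
  cat("<qsar_split>", length(x$calibration), "calibration /",
      length(x$validation), "validation rows (seed", x$seed, ")\n")
  invisible(x)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
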