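#' Leave-one-out cross-validation statistics for a descriptor subset
#'
#' Deleted residuals come from the hat-matrix identity
#' `e_(i) = e_i / (1 - h_ii)` (equivalent to refitting without compound i);
#' `method = "refit"` does the explicit n-fold refit loop instead.
#' `Q2_LOO = 1 - PRESS / sum((y - ybar)^2)` and `RMS_CV = sqrt(PRESS / n)`.
#'
#' @param descriptors character vector of column names (or `NULL` for all
#'   columns of `X`).
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param method `"hat"` (default) or `"refit"`.
#' @return named numeric vector `c(q2_loo =, rms_cv =)`.
#' @export
q2_loo <- function(descriptors, X, y, method = c("hat", "refit")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (!is.null(descriptors)) X <- X[, descriptors, drop = FALSE]
  n <- length(y)
  if (method == "hat") {
    fit <- fit_ols(X, y)
    press <- sum((fit$residuals / (1 - fit$leverage))^2)
  } else {
    press <- 0
    for (i in seq_len(n)) {
      f <- fit_ols(X[-i, , drop = FALSE], y[-i])
      pred <- drop(c(1, X[i, ]) %*% f$coefficients)
      press <- press + (y[i] - pred)^2
    }
  }
  tss <- sum((y - mean(y))^2)
  c(q2_loo = 1 - press / tss, rms_cv = sqrt(press / n))
}

#' Squared correlation of prediction (R2_p)
#'
#' Squared Pearson correlation between predicted and observed activities on
#' a validation set. Being correlation-based it is blind to sign and scale
#' of the predictions (predictions equal to minus the observations also
#' give 1); it measures ranking/linearity, not accuracy.
#'
#' @param model a fitted model with a `predict` method (`qsar_lm`,
#'   `pls_model`, ...).
#' @param X_val validation descriptor matrix.
#' @param y_val validation activities.
#' @return R2_p, or `NA` when either vector has zero variance.
#' @export
r2_prediction <- function(model, X_val, y_val) {
  pred <- predict(model, X_val)
  if (stats::sd(pred) == 0 || stats::sd(y_val) == 0) return(NA_real_)
  stats::cor(pred, y_val)^2
}

#' Y-randomization (response permutation) test
#'
#' Refits the model with the same descriptor subset on seeded random
#' permutations of the activity vector; a model that owes its fit to real
#' structure-activity signal must beat every permuted refit on both R2 and
#' Q2_LOO. The identity permutation is excluded (redrawn).
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param descriptors descriptor subset to refit (fixed; only coefficients
#'   are re-estimated).
#' @param n_iter number of permutations (default 10).
#' @param seed RNG seed.
#' @return data.frame with columns `iteration`, `r2`, `q2_loo`, plus
#'   attributes `original` (the unpermuted R2/Q2) and `all_below` (logical).
#' @export
y_randomization <- function(X, y, descriptors, n_iter = 10, seed = 1L) {
  X <- as.matrix(X)
  Xs <- X[, descriptors, drop = FALSE]
  orig <- fit_ols(Xs, y)
  out <- data.frame(iteration = integer(), r2 = numeric(),
                    q2_loo = numeric())
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    repeat {
      perm <- sample.int(length(y))
      if (!identical(perm, seq_along(y))) break
    }
    f <- fit_ols(Xs, y[perm])
    out <- rbind(out, data.frame(iteration = it, r2 = f$r2_c,
                                 q2_loo = f$q2_loo))
  }
  attr(out, "original") <- c(r2 = orig$r2_c, q2_loo = orig$q2_loo)
  attr(out, "all_below") <- n_iter == 0 ||
    (all(out$r2 < orig$r2_c) && all(out$q2_loo < orig$q2_loo))
  out
}

#' Warning leverage for the applicability domain
#'
#' `h* = 3 (k + 1) / n`, with k the number of model descriptors and n the
#' calibration-set size: compounds with leverage above h* are structurally
#' outside the model's chemical domain. A 5-descriptor model calibrated on
#' 24 compounds has h* = 0.75.
#'
#' @param k number of model descriptors.
#' @param n calibration-set size.
#' @return h*.
#' @export
warning_leverage <- function(k, n) {
  stopifnot(n > 0)
  3 * (k + 1) / n
}

#' Williams-plot table (applicability domain)
#'
#' For every calibration and validation compound: the leverage
#' `h_q = x_q' (X_c' X_c)^-1 x_q` with respect to the intercept-augmented
#' calibration design restricted to the model's descriptors, and the
#' standardized residual (raw residual over the calibration residual
#' standard error, or over the per-point deleted standard error with
#' `residual_scale = "deleted"`). Compounds with |standardized residual| >
#' `sd_limit` are response outliers; compounds with `h > h*` are
#' structurally influential (calibration) or outside the domain
#' (validation).
#'
#' @param model a fitted `qsar_lm`.
#' @param X_cal,y_cal calibration descriptor matrix and activities.
#' @param X_val,y_val optional validation set.
#' @param sd_limit standardized-residual threshold (default 2).
#' @param residual_scale `"model_se"` (default) or `"deleted"`.
#' @return object of class `williams_table`: data.frame with columns `id`,
#'   `set`, `leverage`, `std_residual`, `response_outlier`,
#'   `high_leverage`; attribute `h_star`.
#' @export
williams_table <- function(model, X_cal, y_cal, X_val = NULL, y_val = NULL,
                           sd_limit = 2,
                           residual_scale = c("model_se", "deleted")) {
  residual_scale <- match.arg(residual_scale)
  X_cal <- as.matrix(X_cal)
  k <- length(model$descriptors)
  Zc <- cbind(1, X_cal[, model$descriptors, drop = FALSE])
  XtX <- crossprod(Zc)
  XtXinv <- tryCatch(solve(XtX),
                     error = function(e) stop("singular calibration design"))
  lev <- function(Z) rowSums((Z %*% XtXinv) * Z)
  ids_c <- rownames(X_cal)
  if (is.null(ids_c)) ids_c <- paste0("cal", seq_len(nrow(X_cal)))
  h_c <- lev(Zc)
  res_c <- y_cal - predict(model, X_cal)
  denom <- if (residual_scale == "model_se") model$sigma else
    model$sigma * sqrt(pmax(1 - h_c, .Machine$double.eps))
  tab <- data.frame(id = ids_c, set = "calibration", leverage = h_c,
                    std_residual = res_c / denom, stringsAsFactors = FALSE)
  if (!is.null(X_val)) {
    X_val <- as.matrix(X_val)
    ids_v <- rownames(X_val)
    if (is.null(ids_v)) ids_v <- paste0("val", seq_len(nrow(X_val)))
    Zv <- cbind(1, X_val[, model$descriptors, drop = FALSE])
    res_v <- y_val - predict(model, X_val)
    tab <- rbind(tab, data.frame(id = ids_v, set = "validation",
                                 leverage = lev(Zv),
                                 std_residual = res_v / model$sigma,
                                 stringsAsFactors = FALSE))
  }
  h_star <- warning_leverage(k, nrow(X_cal))
  tab$response_outlier <- abs(tab$std_residual) > sd_limit
  tab$high_leverage <- tab$leverage > h_star
  rownames(tab) <- NULL
  structure(tab, h_star = h_star, sd_limit = sd_limit,
            class = c("williams_table", "data.frame"))
}

#' Plot a Williams table
#'
#' Standardized residual versus leverage with the warning-leverage vertical
#' line and the +/- residual limits; validation compounds are drawn as
#' filled triangles.
#'
#' @param x a [williams_table()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.williams_table <- function(x, ...) {
  h_star <- attr(x, "h_star"); lim <- attr(x, "sd_limit")
  pch <- ifelse(x$set == "calibration", 1, 17)
  ylim <- range(c(x$std_residual, -lim - 0.5, lim + 0.5))
  xlim <- range(c(0, x$leverage, h_star * 1.1))
  graphics::plot(x$leverage, x$std_residual, pch = pch, xlim = xlim,
                 ylim = ylim, xlab = "Leverage (h)",
                 ylab = "Standardized residual", ...)
  graphics::abline(v = h_star, lty = 2)
  graphics::abline(h = c(-lim, lim), lty = 3)
  graphics::legend("topright", pch = c(1, 17),
                   legend = c("calibration", "validation"), bty = "n")
  invisible(x)
}
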