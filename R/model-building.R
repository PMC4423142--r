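#' Fit an ordinary least-squares QSAR model
#'
#' Least squares of activity on a set of descriptor columns with an
#' intercept. Besides the calibration statistics (R2_c and the residual
#' standard error S.E), the leave-one-out cross-validation statistics
#' Q2_LOO and RMS_CV are computed at fit time through the hat-matrix
#' shortcut for deleted residuals, `e_i / (1 - h_ii)`.
#'
#' @param X numeric matrix of descriptor columns for the calibration set
#'   (may have zero columns for an intercept-only model).
#' @param y activity vector.
#' @return object of class `qsar_lm`: descriptor names, `coefficients`
#'   (intercept first), `se`, `n`, `r2_c`, `sigma` (S.E), `q2_loo`,
#'   `rms_cv`, residuals and fitted values.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) X <- matrix(numeric(), length(y), 0L)
  if (ncol(X) && is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y))
  n <- length(y)
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  if (n <= p)
    stop("need more observations (", n, ") than parameters (", p, ")")
  qrx <- qr(Xd)
  if (qrx$rank < p)
    stop("descriptor matrix is rank deficient with the intercept")
  beta <- qr.coef(qrx, y)
  fit <- drop(Xd %*% beta)
  res <- y - fit
  rss <- sum(res^2)
  df <- n - p
  sigma <- sqrt(rss / df)
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sigma * sqrt(diag(XtXinv))
  tss <- sum((y - mean(y))^2)
  h <- rowSums(qr.Q(qrx)^2)
  press <- sum((res / (1 - h))^2)
  structure(
    list(descriptors = colnames(X), coefficients = beta,
         se = stats::setNames(se, names(beta)), n = n,
         r2_c = if (tss > 0) 1 - rss / tss else NA_real_,
         sigma = sigma, q2_loo = if (tss > 0) 1 - press / tss else NA_real_,
         rms_cv = sqrt(press / n), r2_p = NA_real_,
         residuals = res, fitted = fit, leverage = h,
         xtx_inv = XtXinv, y = y),
    class = "qsar_lm")
}

#' @export
print.qsar_lm <- function(x, digits = 4, ...) {
  k <- length(x$descriptors)
  cat("<qsar_lm> pIC50 ~", if (k) paste(x$descriptors, collapse = " + ")
      else "1", "\n")
  co <- formatC(x$coefficients, digits = digits, format = "g")
  se <- formatC(x$se, digits = 3, format = "g")
  cat(paste0("  ", names(x$coefficients), " = ", co, " (+/-", se, ")",
             collapse = "\n"), "\n")
  cat(sprintf("  N = %d, R2_c = %.3f, S.E = %.3f, Q2_LOO = %.3f, RMS_CV = %.3f\n",
              x$n, x$r2_c, x$sigma, x$q2_loo, x$rms_cv))
  if (is.finite(x$r2_p)) cat(sprintf("  R2_p = %.3f\n", x$r2_p))
  invisible(x)
}

#' @export
summary.qsar_lm <- function(object, ...) {
  tval <- object$coefficients / object$se
  df <- object$n - length(object$coefficients)
  tab <- cbind(Estimate = object$coefficients, `Std.Error` = object$se,
               `t value` = tval,
               `Pr(>|t|)` = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  out <- list(coefficients = tab, n = object$n, r2_c = object$r2_c,
              sigma = object$sigma, q2_loo = object$q2_loo,
              rms_cv = object$rms_cv)
  class(out) <- "summary.qsar_lm"
  out
}

#' @export
print.summary.qsar_lm <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat(sprintf("N = %d, R2_c = %.3f, S.E = %.3f, Q2_LOO = %.3f, RMS_CV = %.3f\n",
              x$n, x$r2_c, x$sigma, x$q2_loo, x$rms_cv))
  invisible(x)
}

#' @export
coef.qsar_lm <- function(object, ...) object$coefficients

#' @export
residuals.qsar_lm <- function(object, ...) object$residuals

#' @export
fitted.qsar_lm <- function(object, ...) object$fitted

#' @export
predict.qsar_lm <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$descriptors))
      stop("newdata has ", ncol(newdata), " unnamed columns; the model has ",
           length(object$descriptors), " descriptors")
    Z <- newdata
  } else {
    miss <- setdiff(object$descriptors, colnames(newdata))
    if (length(miss))
      stop("newdata is missing descriptor(s): ", paste(miss, collapse = ", "))
    Z <- newdata[, object$descriptors, drop = FALSE]
  }
  drop(cbind(1, Z) %*% object$coefficients)
}

# Fast forward-step scan: for the current QR (design Q) and residual r,
# return the partial-F p-value of adding each candidate column.
forward_pvalues <- function(Q, r, Z, df_new) {
  Zp <- Z - Q %*% crossprod(Q, Z)      # candidates orthogonal to design
  nrm2 <- colSums(Zp^2)
  rss <- sum(r^2)
  gain <- colSums(Zp * r)^2 / nrm2
  gain[nrm2 < 1e-10] <- NA             # candidate inside current span
  rss_new <- rss - gain
  Fstat <- gain / (rss_new / df_new)
  Fstat[rss_new <= 0] <- Inf
  stats::pf(Fstat, 1, df_new, lower.tail = FALSE)
}

#' Stepwise multiple linear regression
#'
#' Classic forward-entry / backward-removal stepwise selection on partial-F
#' p-values: each cycle adds the candidate with the smallest entry p-value
#' below `p_enter`, then removes any included descriptor whose removal
#' p-value exceeds `p_remove`, until a fixed point or `max_terms` included
#' descriptors. Ties (identical p-values, e.g. duplicated columns) are
#' broken by column order, so the procedure is deterministic.
#'
#' @param X calibration descriptor matrix.
#' @param y calibration activity vector.
#' @param p_enter entry threshold on the partial-F p-value (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param max_terms maximum number of descriptors (default `round(n/5)`,
#'   the usual QSAR rule of thumb of one descriptor per five compounds).
#' @param adjust `"none"` (default) compares the raw minimum p-value with
#'   `p_enter`, as classic stepwise does; `"sidak"` corrects the best
#'   candidate's entry p-value for the number of candidates scanned,
#'   `p_adj = 1 - (1 - p)^m`, making the pure-noise entry probability
#'   family-wise ~`p_enter` regardless of pool size. Uncorrected entry
#'   over a large pool admits spurious descriptors essentially every
#'   cycle (the minimum of hundreds of uniform p-values is < 0.05), which
#'   is why model growth is capped by `max_terms` and why the CDFS
#'   wrapper prunes by cross-validation afterwards.
#' @param max_cycles hard cap on add/remove cycles (guards against
#'   deterministic add-remove oscillation near the term cap).
#' @return a `qsar_lm` fitted on the selected descriptors, with attribute
#'   `"path"` listing the selected-descriptor sets visited after each
#'   cycle. Warns and returns the intercept-only model when nothing enters.
#' @export
stepwise_mlr <- function(X, y, p_enter = 0.05, p_remove = 0.10,
                         max_terms = NULL, adjust = c("none", "sidak"),
                         max_cycles = 50L) {
  adjust <- match.arg(adjust)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(n > 3L, nrow(X) == n)
  if (is.null(max_terms)) max_terms <- max(1L, round(n / 5))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sel <- integer()
  path <- list()
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    changed <- FALSE
    if (length(sel) < max_terms && length(sel) < ncol(X)) {
      Xd <- cbind(1, X[, sel, drop = FALSE])
      qrx <- qr(Xd)
      Q <- qr.Q(qrx)
      r <- drop(y - Q %*% crossprod(Q, y))
      cand <- setdiff(seq_len(ncol(X)), sel)
      df_new <- n - (length(sel) + 2L)
      if (df_new >= 1L) {
        pv <- forward_pvalues(Q, r, X[, cand, drop = FALSE], df_new)
        valid <- which(!is.na(pv))
        if (length(valid)) {
          best <- valid[order(pv[valid], cand[valid])][1L] # ties: earlier column
          p_best <- pv[best]
          if (adjust == "sidak")
            p_best <- 1 - (1 - p_best)^length(valid)
          if (p_best < p_enter) {
            sel <- c(sel, cand[best])
            changed <- TRUE
          }
        }
      }
    }
    if (length(sel)) {
      repeat {
        fit <- fit_ols(X[, sel, drop = FALSE], y)
        tval <- fit$coefficients[-1L] / fit$se[-1L]
        prem <- 2 * stats::pt(abs(tval), n - length(sel) - 1L,
                              lower.tail = FALSE)
        worst <- which.max(prem)
        if (prem[worst] > p_remove) {
          sel <- sel[-worst]
          changed <- TRUE
          if (!length(sel)) break
        } else break
      }
    }
    path[[length(path) + 1L]] <- colnames(X)[sel]
    if (!changed || cycle >= max_cycles) break
  }
  if (!length(sel)) {
    warning("no descriptor met the entry criterion; intercept-only model")
    fit <- fit_ols(X[, integer(), drop = FALSE], y)
  } else {
    fit <- fit_ols(X[, sel, drop = FALSE], y)
  }
  attr(fit, "path") <- unique(path)
  fit
}

#' Combined data splitting-feature selection (CDFS)
#'
#' Because a single calibration/validation split strongly influences which
#' descriptors a stepwise search keeps, CDFS repeats the split `n_splits`
#' times (seeded), runs stepwise MLR on each calibration subset, retains
#' the per-split models whose calibration R2_c exceeds `keep_threshold`,
#' pools the union of their descriptors, and finally runs one more stepwise
#' search restricted to the pooled set on a designated split. Among the
#' nested models visited on that final stepwise path, the model maximizing
#' Q2_LOO is returned (ties broken towards fewer descriptors).
#'
#' @param X descriptor matrix (all compounds).
#' @param y activity vector.
#' @param n_splits number of random subdivisions (default 10).
#' @param keep_threshold retention threshold; interpreted as R2_c by
#'   default, as the correlation coefficient R when
#'   `threshold_on = "r"`.
#' @param validation_fraction per-split hold-out fraction (default 0.2).
#' @param seed master seed; split s uses `seed + s`.
#' @param final_split split used for the pooled-set stepwise: `"fresh"`
#'   (a new seeded split, default) or an integer in `1..n_splits`.
#' @param threshold_on `"r2"` or `"r"`.
#' @param max_terms term cap for the per-split stepwise searches (default:
#'   the [stepwise_mlr()] default, one descriptor per five compounds).
#' @param final_max_terms term cap for the pooled-set stepwise (default
#'   `round(n_calibration / 3)`): the final search needs churn room so
#'   that spurious descriptors that enter the greedy path can later be
#'   displaced, and the model is pruned back by cross-validation anyway.
#' @param q2_tol parsimony tolerance for the general-model choice: among
#'   all candidate descriptor subsets (the stepwise path plus a
#'   Q2-guided backward-elimination sequence from the final stepwise
#'   model), the smallest subset whose Q2_LOO is within `q2_tol` of the
#'   maximum is returned. A pure Q2 maximum systematically keeps spurious
#'   descriptors, because a descriptor picked by the search for its
#'   chance correlation with the calibration residuals also inflates the
#'   leave-one-out statistic; differences below ~0.01 in Q2 at two dozen
#'   compounds are noise, not evidence for a bigger model.
#' @param ... passed to [stepwise_mlr()].
#' @return object of class `cdfs_result`: `models` (retained per-split
#'   fits), `splits`, `pooled` (descriptor union), `general_model`
#'   (a `qsar_lm` carrying R2_p on its validation split), `seed`.
#' @export
cdfs_general_model <- function(X, y, n_splits = 10, keep_threshold = 0.95,
                               validation_fraction = 0.2, seed = 1L,
                               final_split = "fresh",
                               threshold_on = c("r2", "r"),
                               max_terms = NULL, final_max_terms = NULL,
                               q2_tol = 0.01, ...) {
  threshold_on <- match.arg(threshold_on)
  X <- as.matrix(X)
  n_cal <- nrow(X) - round(validation_fraction * nrow(X))
  if (is.null(final_max_terms))
    final_max_terms <- max(1L, round(n_cal / 3))
  models <- list(); splits <- list()
  for (s in seq_len(n_splits)) {
    sp <- split_calibration_validation(X, y, validation_fraction,
                                       seed = seed + s)
    fit <- stepwise_mlr(X[sp$calibration, , drop = FALSE],
                        y[sp$calibration], max_terms = max_terms, ...)
    fit$r2_p <- r2_prediction(fit, X[sp$validation, , drop = FALSE],
                              y[sp$validation])
    stat <- if (threshold_on == "r2") fit$r2_c else sqrt(max(fit$r2_c, 0))
    splits[[s]] <- sp
    if (length(fit$descriptors) && stat > keep_threshold)
      models[[length(models) + 1L]] <- fit
  }
  if (!length(models))
    stop("no split produced a model with calibration fit above ",
         keep_threshold, "; consider lowering keep_threshold")
  pooled <- unique(unlist(lapply(models, `[[`, "descriptors")))
  if (identical(final_split, "fresh")) {
    fsp <- split_calibration_validation(X, y, validation_fraction,
                                        seed = seed + n_splits + 1L)
  } else {
    fsp <- splits[[final_split]]
  }
  Xc <- X[fsp$calibration, pooled, drop = FALSE]
  yc <- y[fsp$calibration]
  final <- stepwise_mlr(Xc, yc, max_terms = final_max_terms, ...)
  # candidate subsets: the stepwise path, plus a Q2-guided backward
  # elimination from the final stepwise model (the exact true subset is
  # often skipped over by the greedy path but reached by elimination)
  cand_sets <- Filter(length, attr(final, "path"))
  S <- final$descriptors
  while (length(S) > 1L) {
    q2s <- vapply(seq_along(S), function(i)
      fit_ols(Xc[, S[-i], drop = FALSE], yc)$q2_loo, 0)
    S <- S[-which.max(q2s)]
    cand_sets[[length(cand_sets) + 1L]] <- S
  }
  cand_sets <- unique(cand_sets)
  fits <- lapply(cand_sets, function(d) fit_ols(Xc[, d, drop = FALSE], yc))
  q2 <- vapply(fits, `[[`, 0, "q2_loo")
  sizes <- lengths(cand_sets)
  ok <- which(q2 >= max(q2) - q2_tol)     # smallest within tolerance of best
  best <- ok[order(sizes[ok], -q2[ok])][1L]
  general <- fits[[best]]
  general$r2_p <- r2_prediction(general, X[fsp$validation, , drop = FALSE],
                                y[fsp$validation])
  structure(list(models = models, splits = splits, pooled = pooled,
                 general_model = general, final_split = fsp,
                 seed = as.integer(seed)),
            class = "cdfs_result")
}

#' @export
print.cdfs_result <- function(x, ...) {
  cat("<cdfs_result>", length(x$models), "retained split model(s); pooled",
      length(x$pooled), "descriptors\n")
  cat("General model:\n")
  print(x$general_model)
  invisible(x)
}

#' Table of per-split CDFS models
#'
#' One row per retained split model plus the general model, mirroring the
#' usual report layout (descriptors used, R2_c, S.E, R2_p, Q2_LOO, RMS_CV).
#'
#' @param x a `cdfs_result`.
#' @return data.frame.
#' @export
cdfs_report <- function(x) {
  row <- function(fit, label) data.frame(
    model = label,
    descriptors = paste(fit$descriptors, collapse = ", "),
    R2_c = fit$r2_c, S.E = fit$sigma, R2_p = fit$r2_p,
    Q2_LOO = fit$q2_loo, RMS_CV = fit$rms_cv,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, c(
    lapply(seq_along(x$models), function(i) row(x$models[[i]], as.character(i))),
    list(row(x$general_model, "general"))))
  rownames(out) <- NULL
  out
}
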