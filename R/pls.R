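# PLS1 core on centered data. Returns weights W, loadings P, y-loadings q,
# scores T and the cumulative original-space coefficient matrix B_all
# (column a = collapsed coefficients of the a-component model), built
# incrementally via r_a = w_a - sum_b r_b (p_b' w_a).
pls_core <- function(Xc, yc, A) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- P <- R <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  B_all <- matrix(0, p, A)
  B <- numeric(p)
  Xd <- Xc; yd <- yc
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                 # X deflated to noise floor
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yd <- yd - qa * t
    r <- w
    if (a > 1L)
      r <- r - R[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(P[, seq_len(a - 1L), drop = FALSE], w)
    B <- B + drop(r) * qa
    W[, a] <- w; P[, a] <- pv; R[, a] <- r; Tm[, a] <- t
    q[a] <- qa; B_all[, a] <- B
    a_used <- a
  }
  list(W = W[, seq_len(a_used), drop = FALSE],
       P = P[, seq_len(a_used), drop = FALSE],
       scores = Tm[, seq_len(a_used), drop = FALSE],
       q = q[seq_len(a_used)],
       B_all = B_all[, seq_len(a_used), drop = FALSE],
       n_components = a_used)
}

#' Fit a partial least squares (PLS1) regression model
#'
#' NIPALS latent decomposition for a single response: columns are centered
#' (not scaled — the final equations are quoted in raw descriptor units),
#' successive latent components maximize covariance with the residual
#' activity, and the latent model is collapsed to ordinary-space
#' coefficients plus intercept so predictions are a plain linear form.
#' With as many components as the rank of the centered descriptor matrix,
#' PLS spans the full column space and reproduces the OLS fit.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param n_components number of latent components A
#'   (`A <= min(n - 1, p)`).
#' @return object of class `pls_model`: `descriptors`, `n_components`,
#'   `coefficients` (original space, named), `intercept`, `scores`,
#'   `loadings`, `weights`, `y_loadings`, fitted values and `r2_c`.
#' @export
pls_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n_components >= 1)
  if (n_components > min(n - 1L, p))
    stop("n_components must be <= min(n - 1, p) = ", min(n - 1L, p))
  if (stats::sd(y) == 0) stop("zero-variance activity vector")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  x_mean <- colMeans(X); y_mean <- mean(y)
  core <- pls_core(sweep(X, 2L, x_mean), y - y_mean, n_components)
  B <- core$B_all[, core$n_components]
  intercept <- y_mean - sum(x_mean * B)
  fitted <- drop(X %*% B) + intercept
  structure(
    list(descriptors = colnames(X), n_components = core$n_components,
         coefficients = stats::setNames(B, colnames(X)),
         intercept = intercept, weights = core$W, loadings = core$P,
         y_loadings = core$q, scores = core$scores,
         x_mean = x_mean, y_mean = y_mean, fitted = fitted,
         residuals = y - fitted,
         r2_c = 1 - sum((y - fitted)^2) / sum((y - y_mean)^2)),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, digits = 4, ...) {
  cat("<pls_model>", length(x$descriptors), "descriptors,",
      x$n_components, "latent component(s)\n")
  cat("  intercept:", formatC(x$intercept, digits = digits, format = "g"),
      "\n  coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  R2_c = %.3f\n", x$r2_c))
  invisible(x)
}

#' @export
coef.pls_model <- function(object, ...)
  c("(Intercept)" = object$intercept, object$coefficients)

#' @export
residuals.pls_model <- function(object, ...) object$residuals

#' @export
fitted.pls_model <- function(object, ...) object$fitted

#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(object$descriptors, colnames(newdata))
    if (length(miss))
      stop("newdata is missing descriptor(s): ", paste(miss, collapse = ", "))
    newdata <- newdata[, object$descriptors, drop = FALSE]
  }
  drop(newdata %*% object$coefficients) + object$intercept
}

# Deleted-prediction PRESS for every component count 1..A in one pass.
pls_loo_press <- function(X, y, A, leave_n = 1L) {
  n <- nrow(X)
  folds <- if (leave_n == 1L) as.list(seq_len(n)) else
    split(seq_len(n), ceiling(seq_len(n) / leave_n))
  press <- numeric(A)
  used_min <- A
  for (f in folds) {
    Xt <- X[-f, , drop = FALSE]; yt <- y[-f]
    nt <- nrow(Xt)
    Amax <- min(A, nt - 1L, ncol(Xt))
    if (Amax < 1L) stop("fold too small for any PLS component")
    xm <- colMeans(Xt); ym <- mean(yt)
    core <- pls_core(Xt - rep(xm, each = nt), yt - ym, Amax)
    used_min <- min(used_min, core$n_components)
    Zv <- X[f, , drop = FALSE] - rep(xm, each = length(f))
    pred <- Zv %*% core$B_all + ym          # one column per component count
    err2 <- (y[f] - pred)^2
    press[seq_len(core$n_components)] <-
      press[seq_len(core$n_components)] + colSums(err2)
  }
  press[seq_len(used_min)]
}

#' Cross-validated Q2 for a PLS model
#'
#' Leave-n-out cross-validation: compounds are held out in consecutive
#' blocks of `leave_n`, the model is refitted on the remainder, and
#' `Q2 = 1 - PRESS / sum((y - ybar)^2)` from the deleted predictions.
#'
#' @param X descriptor matrix.
#' @param y activity vector.
#' @param n_components latent components used in every fold.
#' @param leave_n hold-out block size (default 1 = LOO).
#' @return Q2.
#' @export
pls_cv_q2 <- function(X, y, n_components, leave_n = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  if (n_components > min(n - leave_n - 1L, ncol(X)))
    stop("more components than the smallest training fold allows")
  press <- pls_loo_press(X, y, n_components, leave_n)
  if (length(press) < n_components)
    stop("descriptor matrix rank-exhausted before ", n_components,
         " components")
  1 - press[n_components] / sum((y - mean(y))^2)
}
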