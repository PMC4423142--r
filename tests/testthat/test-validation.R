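test_that("Q2_LOO via the hat shortcut equals the explicit refit loop", {
  set.seed(50)
  for (rep in 1:5) {
    X <- matrix(rnorm(24 * 5), 24, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    y <- drop(X %*% rnorm(5)) + rnorm(24, sd = 0.5)
    expect_equal(q2_loo(NULL, X, y), q2_loo(NULL, X, y, method = "refit"),
                 tolerance = 1e-10)
  }
  # noiseless data: perfect cross-validation
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- 1 + drop(X %*% c(1, 2, 3))
  st <- q2_loo(NULL, X, y)
  expect_equal(st[["q2_loo"]], 1)
  expect_equal(st[["rms_cv"]], 0, tolerance = 1e-10)
  # Q2_LOO never exceeds R2_c (PRESS >= RSS)
  for (rep in 1:10) {
    Xr <- matrix(rnorm(22 * 4), 22, 4)
    yr <- drop(Xr %*% rnorm(4)) + rnorm(22)
    f <- fit_ols(Xr, yr)
    expect_lte(f$q2_loo, f$r2_c)
  }
})

test_that("shuffled activities degrade cross-validated predictivity", {
  qb <- make_qsar_bundle(5)
  X <- qb$bundle$X[, qb$bundle$support]
  y <- qb$bundle$y
  q_true <- q2_loo(NULL, X, y)[["q2_loo"]]
  set.seed(51)
  q_shuf <- q2_loo(NULL, X, sample(y))[["q2_loo"]]
  expect_gt(q_true, q_shuf)
})

test_that("R2_p is the squared prediction correlation, sign-blind", {
  set.seed(52)
  X <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(X %*% c(1, -1)) + rnorm(20, sd = 0.1)
  f <- fit_ols(X, y)
  expect_equal(r2_prediction(f, X, predict(f, X)), 1)
  expect_equal(r2_prediction(f, X, -predict(f, X)), 1)
  expect_true(is.na(r2_prediction(f, X, rep(1, 20))))
  # null distribution: E[r^2] = 1/(n-1) for independent vectors
  set.seed(53)
  r2s <- replicate(1000, cor(rnorm(6), rnorm(6))^2)
  expect_equal(mean(r2s), 1 / 5, tolerance = 0.03)
})

test_that("Y-randomization refits permuted activities reproducibly", {
  qb <- make_qsar_bundle(2)
  X <- qb$bundle$X; y <- qb$bundle$y
  yr <- y_randomization(X, y, qb$bundle$support, n_iter = 10, seed = 4)
  expect_equal(nrow(yr), 10L)
  orig <- attr(yr, "original")
  expect_true(all(yr$r2 < orig[["r2"]]))
  expect_true(all(yr$q2_loo < orig[["q2_loo"]]))
  expect_true(attr(yr, "all_below"))
  # same seed -> identical permutation sequence
  yr2 <- y_randomization(X, y, qb$bundle$support, n_iter = 10, seed = 4)
  expect_identical(yr, yr2)
  # empty table for zero iterations
  yr0 <- y_randomization(X, y, qb$bundle$support, n_iter = 0, seed = 4)
  expect_equal(nrow(yr0), 0L)
})

test_that("warning leverage is 3(k+1)/n", {
  expect_identical(warning_leverage(5, 24), 0.75)
  expect_identical(warning_leverage(0, 3), 1)
  expect_identical(warning_leverage(3, 24), 0.5)
})

test_that("the Williams table flags leverage and residual outliers", {
  set.seed(54)
  n <- 24
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n, sd = 0.3)
  f <- fit_ols(X, y)
  wt <- williams_table(f, X, y)
  # calibration leverages sum to k+1 and live in [1/n, 1]
  expect_equal(sum(wt$leverage), 4, tolerance = 1e-9)
  expect_true(all(wt$leverage >= 1 / n - 1e-12 & wt$leverage <= 1 + 1e-12))
  expect_equal(attr(wt, "h_star"), warning_leverage(3, n))
  # a validation point at the calibration centroid has minimal leverage
  ctr <- matrix(colMeans(X), 1, dimnames = list("ctr", colnames(X)))
  wt2 <- williams_table(f, X, y, ctr, mean(y))
  expect_equal(wt2$leverage[wt2$set == "validation"], 1 / n,
               tolerance = 1e-9)
  # a far-extrapolated point exceeds the warning leverage and is flagged
  far <- matrix(10 * apply(X, 2, sd) + colMeans(X), 1,
                dimnames = list("far", colnames(X)))
  wt3 <- williams_table(f, X, y, far, 0)
  vrow <- wt3[wt3$set == "validation", ]
  expect_gt(vrow$leverage, attr(wt3, "h_star"))
  expect_true(vrow$high_leverage)
  # flags are consistent with the thresholds
  expect_equal(wt3$response_outlier, abs(wt3$std_residual) > 2)
  # plot method draws without error
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(wt3))
})
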