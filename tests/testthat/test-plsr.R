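test_that("mean_center removes means and is invertible", {
  X <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4, byrow = FALSE)
  mc <- mean_center(matrix(rep(c(5, 7, 9), 3), nrow = 3, byrow = TRUE),
                    c(1, 1, 1))
  expect_true(all(mc$Xc == 0)) # identical rows center to zero

  mc2 <- mean_center(matrix(c(1, 2, 3, 4), 2), c(1, 3))
  expect_equal(mc2$yc, c(-1, 1))
  expect_equal(mc2$y_mean, 2)
  expect_equal(sweep(mc2$Xc, 2, mc2$x_mean, "+"),
               matrix(c(1, 2, 3, 4), 2))

  set.seed(1)
  X <- matrix(rnorm(30), 5, 6)
  mc3 <- mean_center(X, rnorm(5))
  expect_true(all(abs(colMeans(mc3$Xc)) < 1e-12 * max(abs(X))))
  expect_lt(abs(mean(mc3$yc)), 1e-12)

  expect_error(mean_center(matrix(1:3, 1), 1), "at least 2")
})

test_that("a perfectly explanatory channel is recovered with one component", {
  set.seed(2)
  y <- c(0.3, 1, 3, 7, 10)
  X <- cbind(2 * y, matrix(rnorm(15), 5, 3))
  fit <- plsr_fit(X, y, ncomp = 1)
  # not exact with other random channels present; use the pure case
  Xpure <- cbind(2 * y)
  fitp <- plsr_fit(Xpure, y, ncomp = 1)
  expect_equal(fitted(fitp), y, tolerance = 1e-10)
  expect_s3_class(fit, "sers_plsr")
})

test_that("full-component NIPALS matches the least-squares oracle", {
  set.seed(3)
  # tall full-rank case: unique OLS solution
  X <- matrix(rnorm(24), 6, 4)
  y <- rnorm(6)
  fit <- plsr_fit(X, y, ncomp = 4)
  mc <- mean_center(X, y)
  b_ols <- lstsq_minnorm(mc$Xc, mc$yc)
  expect_equal(unname(coef(fit)), b_ols, tolerance = 1e-8)
  expect_equal(fitted(fit), drop(mc$Xc %*% b_ols) + mc$y_mean,
               tolerance = 1e-8)

  # wide case: training predictions match the minimum-norm solution
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:12, 1)
    p <- sample(15:40, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    mc <- mean_center(X, y)
    rk <- qr(mc$Xc)$rank
    fit <- plsr_fit(X, y, ncomp = rk)
    pred_oracle <- drop(mc$Xc %*% lstsq_minnorm(mc$Xc, mc$yc)) + mc$y_mean
    expect_equal(fitted(fit), pred_oracle, tolerance = 1e-8)
  }
})

test_that("the first weight maximizes covariance with the response", {
  set.seed(4)
  X <- matrix(rnorm(20 * 15), 20, 15)
  y <- rnorm(20)
  fit <- plsr_fit(X, y, ncomp = 3)
  mc <- mean_center(X, y)

  # analytic direction
  w_exact <- drop(crossprod(mc$Xc, mc$yc))
  w_exact <- w_exact / sqrt(sum(w_exact^2))
  expect_equal(abs(sum(fit$weights[, 1] * w_exact)), 1, tolerance = 1e-10)

  # Monte-Carlo maximization: no random unit direction beats w1
  cov_w1 <- cov(drop(mc$Xc %*% fit$weights[, 1]), y)
  U <- matrix(rnorm(15 * 1e4), ncol = 1e4)
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  cov_rand <- abs(cov(drop(mc$Xc %*% U), y))
  expect_true(all(cov_w1 >= cov_rand))
})

test_that("scores are orthogonal and weights orthonormal on large instances", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 200), 50, 200)
    y <- rnorm(50)
    fit <- plsr_fit(X, y, ncomp = 10)
    Tm <- fit$scores
    G <- crossprod(Tm) / tcrossprod(sqrt(colSums(Tm^2)))
    expect_true(all(abs(G[upper.tri(G)]) < 1e-8))
    WtW <- crossprod(fit$weights)
    expect_true(all(abs(WtW - diag(10)) < 1e-10))
  }
})

test_that("predictions follow the centered-coefficient form", {
  set.seed(5)
  X <- matrix(rnorm(40), 8, 5)
  y <- rnorm(8)
  fit <- plsr_fit(X, y, ncomp = 2)
  expect_equal(unname(predict(fit, rbind(fit$x_mean))), fit$y_mean)

  bzero <- fit
  bzero$coefficients[] <- 0
  expect_equal(unname(predict(bzero, matrix(rnorm(10), 2, 5))),
               rep(fit$y_mean, 2))

  expect_error(predict(fit, matrix(rnorm(8), 2, 4)), "channel mismatch")
})

test_that("response rescaling and shifts propagate exactly", {
  set.seed(6)
  X <- matrix(rnorm(60), 10, 6)
  y <- rnorm(10)
  fit <- plsr_fit(X, y, ncomp = 3)
  lam <- 3.7
  fit_scaled <- plsr_fit(X, lam * y, ncomp = 3)
  expect_equal(unname(coef(fit_scaled)), lam * unname(coef(fit)),
               tolerance = 1e-10)
  expect_equal(fitted(fit_scaled), lam * fitted(fit), tolerance = 1e-10)

  fit_shift <- plsr_fit(X, y + 11, ncomp = 3)
  expect_equal(unname(coef(fit_shift)), unname(coef(fit)), tolerance = 1e-10)
  expect_equal(fitted(fit_shift), fitted(fit) + 11, tolerance = 1e-10)
})

test_that("degenerate deflation stops early with a flag instead of failing", {
  y <- c(1, 2, 3, 4)
  X <- cbind(y, 2 * y, -y) # rank 1 after centering
  fit <- plsr_fit(X, y, ncomp = 3)
  expect_lt(fit$ncomp, 3)
  expect_true(fit$early_stop)
  expect_equal(fitted(fit), y, tolerance = 1e-10)
})

test_that("leave-one-out selection finds the true rank of noiseless mixtures", {
  libs <- tiny_psb_libraries()
  ax <- tiny_axis()
  set <- simulate_dataset(mixture_design(replicates = 1), libs,
                          zero_noise(), ax, seed = 1)
  fm <- extract_windows(set, windows_from_bands(libs$PS, 3), "PS")
  sel <- select_ncomp_cv(fm$X, fm$y, max_ncomp = 6)
  expect_equal(sel$ncomp, 2)
  expect_lt(sel$rmsecv[2], 1e-8)

  expect_equal(select_ncomp_cv(fm$X, fm$y, max_ncomp = 1)$ncomp, 1)
  expect_error(select_ncomp_cv(fm$X[1:2, ], fm$y[1:2], 1), "at least 3")
})

test_that("interference invariance: co-analyte sweep leaves predictions fixed", {
  libs <- tiny_psb_libraries()
  ax <- tiny_axis()
  set <- simulate_dataset(mixture_design(replicates = 1), libs,
                          zero_noise(), ax, seed = 1)
  fm <- extract_windows(set, windows_from_bands(libs$PS, 3), "PS")
  fit <- plsr_fit(fm, ncomp = 2)
  pred <- predict(fit)
  # within each true-PS group, SB sweeps 0..100; predictions must not move
  spread <- tapply(pred, fm$y, function(v) diff(range(v)))
  expect_true(all(spread < 1e-6))
  expect_equal(pred, fm$y, tolerance = 1e-6)
})

test_that("r_squared matches the hand-computed Pearson form", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(r_squared(2 * c(1, 2, 3, 4) + 7, c(1, 2, 3, 4)), 1.0)
  # frozen from the hand computation: r^2 = 6.5^2 / (5 * 8.75)
  expect_equal(r_squared(c(1, 2, 3, 4), c(1, 2, 3, 5)), 42.25 / 43.75)
  # symmetry and affine invariance
  set.seed(8)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(r_squared(a, b), r_squared(b, a))
  expect_equal(r_squared(-2 * a + 3, b), r_squared(a, b))
  expect_error(r_squared(a, rep(1, 10)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("rmse matches the hand computation", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(rmse(c(1, 2, 3) + 2.5, c(1, 2, 3)), 2.5) # pure bias
  expect_error(rmse(1:3, 1:4), "equal length")
})
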