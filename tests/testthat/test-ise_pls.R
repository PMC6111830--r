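test_that("PLS1 reduces to OLS for one predictor and at full rank", {
  set.seed(41)
  x <- rnorm(15)
  y <- 1.5 + 2 * x + rnorm(15, 0, 0.2)
  m <- pls_fit(matrix(x), y, 1)
  expect_equal(m$beta, cov(x, y) / var(x), tolerance = 1e-10)

  for (i in 1:5) {
    X <- matrix(rnorm(12 * 4), 12, 4)
    yy <- rnorm(12)
    m4 <- pls_fit(X, yy, 4)
    ols <- coef(lm(yy ~ X))
    expect_equal(m4$beta, unname(ols[-1]), tolerance = 1e-8)
    expect_equal(m4$intercept, unname(ols[1]), tolerance = 1e-8)
  }
  expect_error(pls_fit(matrix(rnorm(10), 5), rep(3, 5), 1), "variance")
  expect_error(pls_fit(matrix(rnorm(10), 5), rnorm(5), 5), "nlv")
})

test_that("PLS coefficient paths match an independent NIPALS oracle", {
  set.seed(42)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- drop(X %*% rnorm(8)) + rnorm(20, 0, 0.3)
    m <- pls_fit(X, y, 5)
    o <- oracle_pls_path(X, y, 5)
    expect_equal(m$beta_path, o$beta, tolerance = 1e-9)
    expect_equal(m$x_mean, o$x_mean, tolerance = 1e-12)
  }
})

test_that("prediction honours the centering contract", {
  set.seed(43)
  X <- matrix(rnorm(10 * 3), 10, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + 4
  m <- pls_fit(X, y, 3)
  expect_equal(pls_predict(m, X), y, tolerance = 1e-8)        # exact fit
  expect_equal(unname(pls_predict(m, matrix(m$x_mean, 1))), m$y_mean,
               tolerance = 1e-10)
  # affine map: differences of predictions are linear in differences of X
  X1 <- matrix(rnorm(3), 1); X2 <- matrix(rnorm(3), 1)
  expect_equal(pls_predict(m, X1) - pls_predict(m, X2),
               drop((X1 - X2) %*% m$beta), tolerance = 1e-10)
  expect_error(pls_predict(m, matrix(1, 2, 5)), "columns")
})

test_that("LOO cross-validation equals the brute-force per-sample refit", {
  set.seed(44)
  for (i in 1:4) {
    X <- matrix(rnorm(10 * 8), 10, 8)
    y <- drop(X %*% rnorm(8)) + rnorm(10, 0, 0.5)
    cv <- loo_rmse(X, y, 3)
    pred_or <- oracle_loo_pred(X, y, 3)
    expect_equal(cv$y_pred, pred_or, tolerance = 1e-9)
    expect_equal(cv$rmse, sqrt(mean((y - pred_or)^2)), tolerance = 1e-12)
  }
  # Eq-style arithmetic on a frozen pair
  cvh <- hyperchla:::cv_result(c(0, 0), c(3, 4))
  expect_equal(cvh$rmse, sqrt(25 / 2))
})

test_that("LOO-minimum latent-variable selection finds planted rank", {
  set.seed(45)
  n <- 20
  T2 <- matrix(rnorm(n * 2), n, 2)               # two latent factors
  P2 <- matrix(rnorm(2 * 12), 2, 12)
  X <- T2 %*% P2
  y <- drop(T2 %*% c(2, -1))
  k <- select_nlv_by_rmse(X, y, max_nlv = 6)
  expect_equal(as.integer(k), 2L)
  rmse <- attr(k, "rmse")
  expect_lt(rmse[2], rmse[1])
  expect_equal(as.integer(select_nlv_by_rmse(X, y, max_nlv = 1)), 1L)
  expect_identical(as.integer(select_nlv_by_rmse(X, y, 6)), as.integer(k))
})

test_that("predictor importance is a normalised |beta|*sd profile", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = rep(5, 4))
  y <- c(1, 2, 3, 4)
  m <- pls_fit(X, y, 1)
  imp <- importance(m, X)
  expect_equal(sum(imp$z), 1)
  expect_equal(unname(imp$z[3]), 0)              # constant column
  # x2 = 2*x1: w prop (1, 2), sd doubles too, so |beta|*s splits 1:4
  expect_equal(unname(imp$z), c(0.2, 0.8, 0), tolerance = 1e-10)

  # two antisymmetric predictors share the importance equally
  x <- c(0.2, 1.4, -0.8, 2.1, 0.5)
  Xs <- cbind(x, -x)
  ms <- pls_fit(Xs, x, 1)
  expect_equal(unname(importance(ms, Xs)$z), c(0.5, 0.5), tolerance = 1e-12)
  set.seed(46)
  Xr <- matrix(rnorm(30), 10, 3)
  mr <- pls_fit(Xr, rnorm(10), 2)
  expect_equal(sum(importance(mr, Xr)$z), 1, tolerance = 1e-12)
})

test_that("stepwise elimination removes minimum-importance bands one at a time", {
  set.seed(47)
  n <- 25; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, c(5, 20, 35)] %*% c(3, -2, 1.5))   # only 3 informative bands
  res <- ise_eliminate(X, y, max_nlv = 5)
  expect_equal(res$trace$n_bands, seq(p, 2))       # strictly decreasing by 1
  expect_equal(res$trace$rmse[res$best_cycle], min(res$trace$rmse))
  # global-minimum selection can never lose to the full-band starting model
  expect_lte(res$trace$rmse[res$best_cycle], res$trace$rmse[1])
  expect_lt(res$trace$rmse[res$best_cycle], 0.05)  # near-perfect recovery
  expect_equal(sum(res$band_mask), res$trace$n_bands[res$best_cycle])

  # importance normalisation holds at every cycle along the way
  retained <- seq_len(p)
  for (cyc in 1:6) {
    Xr <- X[, retained, drop = FALSE]
    m <- pls_fit(Xr, y, min(5, ncol(Xr)))
    z <- importance(m, Xr)$z
    expect_equal(sum(z), 1, tolerance = 1e-12)
    retained <- retained[-which.min(z)]
  }
})

test_that("jaggedness is the ordered sum of squared coefficient steps", {
  expect_equal(jaggedness(rep(0.3, 7)), 0)
  expect_equal(jaggedness(c(0, 1, 0)), 2)
  expect_equal(jaggedness(c(0, 0, 1)), 1)          # ordering matters
  expect_error(jaggedness(0.5), "at least 2")
})

test_that("final NLV choice balances rescaled LOO RMSE and jaggedness", {
  expect_equal(hyperchla:::rescale01(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(hyperchla:::rescale01(c(3, 3, 3)), c(0, 0, 0))  # degenerate

  set.seed(48)
  for (i in 1:3) {
    X <- matrix(rnorm(14 * 6), 14, 6)
    y <- drop(X %*% rnorm(6)) + rnorm(14, 0, 0.4)
    sel <- select_final_nlv(X, y, max_nlv = 4)
    expect_equal(sel$chosen_nlv, as.integer(oracle_final_nlv(X, y, 4)))
    expect_equal(range(sel$table$rmse_r), c(0, 1))
    expect_equal(range(sel$table$J_r), c(0, 1))
    expect_equal(sel$table$score[sel$chosen_nlv], min(sel$table$score))
  }

  # dominance: a count minimising both terms is always chosen
  doms <- vapply(1:20, function(i) {
    set.seed(100 + i)
    X <- matrix(rnorm(12 * 5), 12, 5)
    y <- drop(X %*% rnorm(5)) + rnorm(12, 0.3)
    sel <- select_final_nlv(X, y, max_nlv = 4)
    jmin <- which.min(sel$table$rmse)
    !(jmin == which.min(sel$table$J)) || sel$chosen_nlv == jmin
  }, logical(1))
  expect_true(all(doms))
})

test_that("the full ISE-PLS pipeline reports a coherent summary", {
  ds <- generate_dataset(synthetic_params(seed = 23))
  rl <- trim_to_analysis_range(savgol_smooth(ds$spectra), 640, 760)
  res <- run_ise_pls(rl, ds$chl)
  expect_s3_class(res, "ise_pls_result")
  expect_equal(res$n, 59)
  expect_equal(res$n_selected, length(res$selected_wavelengths))
  expect_equal(res$percentage,
               selected_percentage(res$n_selected, length(rl$wavelengths)))
  expect_equal(res$validation$rmse,
               sqrt(mean((res$validation$y_obs - res$validation$y_pred)^2)))
  expect_equal(res$validation$rpd,
               sd_population(ds$chl$chl) / res$validation$rmse)
  # FDR input is accepted identically to RL input
  fdr <- first_derivative(rl)
  resf <- run_ise_pls(fdr, ds$chl)
  expect_s3_class(resf, "ise_pls_result")
  expect_equal(resf$kind, "FDR")
})

test_that("cleaner data never hurts: LOO RMSE grows with generator noise", {
  rmse_at <- function(mult) {
    ds <- generate_dataset(synthetic_params(
      seed = 29, noise_sd_multiplicative = mult,
      noise_sd_additive = mult * 5e-3))
    rl <- trim_to_analysis_range(savgol_smooth(ds$spectra), 640, 760)
    run_ise_pls(rl, ds$chl)$validation$rmse
  }
  r <- vapply(c(0, 0.02, 0.08), rmse_at, numeric(1))
  # allow sampling-error slack on the matched-seed comparison
  expect_lte(r[1], r[2] * 1.25)
  expect_lte(r[2], r[3] * 1.25)
})
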