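test_that("OLS closed form matches lm on a seeded instance", {
  set.seed(41)
  x1 <- rnorm(200); x2 <- rnorm(200)
  y <- 0.5 - 1.3 * x1 + 0.8 * x2 + rnorm(200)
  fit <- ols_fit(y, x1, x2)
  m <- lm(y ~ x1 + x2)
  expect_equal(c(fit$beta0, fit$beta1, fit$beta2), unname(coef(m)),
               tolerance = 1e-10)
  expect_equal(c(fit$var1, fit$var2), unname(diag(vcov(m))[2:3]),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(m)$r.squared, tolerance = 1e-10)
  expect_equal(fit$residuals, unname(residuals(m)), tolerance = 1e-10)
  expect_lt(abs(mean(fit$residuals)), 1e-12)
})

test_that("OLS recovers exact linear relations and handles degenerate means", {
  set.seed(43)
  x1 <- rnorm(50); x2 <- runif(50)
  fit <- ols_fit(1 + x1 + 2 * x2, x1, x2)
  expect_equal(c(fit$beta1, fit$beta2), c(1, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # centered regressor has zero elasticity whatever its coefficient
  x2c <- x2 - mean(x2)
  fit <- ols_fit(5 + x1 + 7 * x2c, x1, x2c)
  expect_equal(fit$eta2, 0, tolerance = 1e-10)
  # zero-mean response: elasticity undefined and flagged
  y <- x1 + x2
  fit <- ols_fit(y - mean(y), x1, x2)
  expect_false(fit$eta_defined)
  expect_true(is.na(fit$eta1))
  expect_error(ols_fit(rnorm(50), x1, 2 * x1),
               class = "dfareg_degenerate_error")
})

test_that("scale-dependent coefficients recover exact relations at all scales", {
  set.seed(47)
  x1 <- cumsum(rnorm(600)); x2 <- rnorm(600)
  fit <- dfa_fit(1 + x1 + 2 * x2, x1, x2, grid = c(10, 30, 100, 150))
  expect_true(all(fit$table$usable))
  expect_equal(fit$table$beta1, rep(1, 4), tolerance = 1e-8)
  expect_equal(fit$table$beta2, rep(2, 4), tolerance = 1e-8)
  expect_equal(fit$table$r2, rep(1, 4), tolerance = 1e-8)
})

test_that("per-scale coefficients equal the oracle-assembled closed form", {
  set.seed(53)
  x1 <- rnorm(256); x2 <- rnorm(256)
  y <- 1 + x1 + 2 * x2 + rnorm(256)
  fit <- dfa_fit(y, x1, x2, grid = c(16, 32))
  for (g in 1:2) {
    ob <- oracle_dfa_betas(y, x1, x2, fit$grid[g])
    expect_equal(fit$table$beta1[g], unname(ob["beta1"]), tolerance = 1e-10)
    expect_equal(fit$table$beta2[g], unname(ob["beta2"]), tolerance = 1e-10)
  }
})

test_that("residual fluctuation satisfies the bilinear expansion", {
  # recomputing e(n) and running DFA at the same scale must agree with the
  # expansion of F2_eps in the six stored fluctuation functions, because
  # profile construction and detrending are linear
  set.seed(59)
  x1 <- cumsum(rnorm(400)); x2 <- cumsum(rnorm(400))
  y <- 2 + 0.5 * x1 - 1.2 * x2 + rnorm(400, sd = 3)
  grid <- c(10, 25, 60)
  fit <- dfa_fit(y, x1, x2, grid = grid)
  fyy <- dfa_variance(y, grid)$f2
  f11 <- dfa_variance(x1, grid)$f2
  f22 <- dfa_variance(x2, grid)$f2
  f12 <- dcca_covariance(x1, x2, grid)$f2
  f1y <- dcca_covariance(x1, y, grid)$f2
  f2y <- dcca_covariance(x2, y, grid)$f2
  b1 <- fit$table$beta1; b2 <- fit$table$beta2
  expansion <- fyy + b1^2 * f11 + b2^2 * f22 -
    2 * b1 * f1y - 2 * b2 * f2y + 2 * b1 * b2 * f12
  expect_equal(fit$table$fe2, expansion, tolerance = 1e-8)
  # and the determination coefficient is exactly 1 - F2_eps / F2_Y
  expect_equal(fit$table$r2, 1 - fit$table$fe2 / fit$table$f2_y,
               tolerance = 1e-12)
})

test_that("coefficients transform correctly under rescaling and shifts", {
  set.seed(61)
  x1 <- cumsum(rnorm(500)); x2 <- rnorm(500)
  y <- 1 + x1 + 2 * x2 + rnorm(500)
  grid <- c(10, 40, 120)
  base <- dfa_fit(y, x1, x2, grid = grid)
  scaled <- dfa_fit(y, 4 * x1, x2, grid = grid)
  expect_equal(scaled$table$beta1, base$table$beta1 / 4, tolerance = 1e-8)
  expect_equal(scaled$table$beta2, base$table$beta2, tolerance = 1e-8)
  # standardized coefficients absorb positive rescaling
  expect_equal(scaled$table$beta_star1, base$table$beta_star1,
               tolerance = 1e-8)
  shifted <- dfa_fit(y + 3, x1 - 11, x2 + 7, grid = grid)
  expect_equal(shifted$table$beta1, base$table$beta1, tolerance = 1e-8)
  expect_equal(shifted$table$beta2, base$table$beta2, tolerance = 1e-8)
})

test_that("scale averaging is the plain mean over usable scales in range", {
  set.seed(67)
  x1 <- rnorm(400); x2 <- rnorm(400)
  y <- 1 + x1 + 2 * x2 + rnorm(400)
  fit <- dfa_fit(y, x1, x2, grid = c(10, 20, 40, 80))
  avg <- average_over_scales(fit, 20, 80)
  expect_equal(unname(avg["beta1"]), mean(fit$table$beta1[2:4]))
  expect_equal(unname(avg["beta2"]), mean(fit$table$beta2[2:4]))
  single <- average_over_scales(fit, 40, 40)
  expect_equal(unname(single["beta1"]), fit$table$beta1[3])
  expect_error(average_over_scales(fit, 200, 300),
               class = "dfareg_param_error")
})
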