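test_that("allometry fit recovers exact power laws", {
  size <- c(100, 150, 230, 320, 410)
  # lm warns about the essentially perfect fit; that is the point here
  a2 <- suppressWarnings(allometry_fit(size, 0.7 * size^2,
                                       expected_slope = 2))
  expect_equal(a2$slope, 2, tolerance = 1e-10)
  expect_equal(a2$r_squared, 1, tolerance = 1e-12)  # zero residual SS
  a1 <- suppressWarnings(allometry_fit(size, 3 * size, expected_slope = 1))
  expect_equal(a1$slope, 1, tolerance = 1e-10)
  expect_error(allometry_fit(size[1:2], size[1:2], 1), "at least 3")
  expect_error(allometry_fit(c(1, 2, -3), c(1, 2, 3), 1),
               "invalid measurement")
})

test_that("allometry slope matches the normal-equation oracle on noisy data", {
  set.seed(42)
  for (i in 1:10) {
    size <- exp(runif(30, 4, 7))
    trait <- exp(1 + 1.8 * log(size) + rnorm(30, 0, 0.2))
    fit <- allometry_fit(size, trait, expected_slope = 2)
    X <- cbind(1, log(size))
    o <- ols_oracle(log(trait), X)
    expect_equal(fit$slope, o$beta[2], tolerance = 1e-10)
    expect_equal(fit$intercept, o$beta[1], tolerance = 1e-10)
    expect_equal(fit$slope_se, unname(o$se[2]), tolerance = 1e-10)
  }
})

test_that("allometry CI covers a known slope in at least 90% of simulations", {
  set.seed(7)
  hits <- 0
  for (i in 1:200) {
    size <- exp(runif(40, 4, 7))
    trait <- exp(0.5 + 2 * log(size) + rnorm(40, 0, 0.3))
    ci <- allometry_fit(size, trait, expected_slope = 2)$slope_ci
    hits <- hits + (ci[1] <= 2 && 2 <= ci[2])
  }
  expect_gte(hits / 200, 0.90)
})

test_that("multiple regression equals the pseudoinverse oracle", {
  set.seed(5)
  n <- 40
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n), c = runif(n))
  y <- drop(X %*% c(1, 2, -0.5, 0.3)) + rnorm(n)
  fit <- multiple_regression(y, X)
  o <- ols_oracle(y, X)
  expect_equal(unname(fit$coefficients), unname(o$beta), tolerance = 1e-10)
  expect_equal(unname(fit$standard_errors), unname(o$se), tolerance = 1e-10)
  expect_equal(fit$df, n - 4L)
  # single predictor reduces to simple regression
  f1 <- multiple_regression(y, X[, 1:2])
  lm1 <- lm(y ~ X[, 2])
  expect_equal(unname(f1$coefficients), unname(coef(lm1)), tolerance = 1e-10)
  expect_equal(unname(f1$p_values),
               unname(summary(lm1)$coefficients[, 4]), tolerance = 1e-10)
})

test_that("orthogonal predictors decouple into univariate slopes", {
  n <- 32
  a <- rep(c(-1, 1), n / 2)
  b <- rep(c(-1, -1, 1, 1), n / 4)   # orthogonal to a and to the intercept
  set.seed(13)
  y <- 1 + 2 * a - 3 * b + rnorm(n)
  fit <- multiple_regression(y, cbind(intercept = 1, a = a, b = b))
  expect_equal(unname(fit$coefficients["a"]),
               unname(coef(lm(y ~ a))[2]), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["b"]),
               unname(coef(lm(y ~ b))[2]), tolerance = 1e-10)
})

test_that("rank deficiency is rejected with the collinear column named", {
  n <- 20
  a <- rnorm(n)
  X <- cbind(intercept = 1, a = a, twice_a = 2 * a)
  expect_error(multiple_regression(rnorm(n), X), "twice_a")
})

test_that("trait correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(trait_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(trait_correlation(x, -x)$r, -1)
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(25); b <- 0.5 * a + rnorm(25)
    got <- trait_correlation(a, b)
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(got$r, r_oracle, tolerance = 1e-12)
    t_oracle <- r_oracle * sqrt(23 / (1 - r_oracle^2))
    expect_equal(got$p, 2 * pt(-abs(t_oracle), 23), tolerance = 1e-12)
  }
  expect_error(trait_correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(trait_correlation(1:2, 1:2), "at least 3")
})
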