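test_that("bm_loglik with identity covariance is the iid normal density", {
  set.seed(1)
  n <- 12
  x <- setNames(rnorm(n, 5, 2), sprintf("t%02d", 1:n))
  V <- diag(n); dimnames(V) <- list(names(x), names(x))
  got <- bm_loglik(x, V)
  m <- mean(x); s2 <- mean((x - m)^2)
  expect_equal(got$root_mean, m, tolerance = 1e-12)
  expect_equal(got$sigma2, s2, tolerance = 1e-12)
  expect_equal(got$loglik, sum(dnorm(x, m, sqrt(s2), log = TRUE)),
               tolerance = 1e-10)
})

test_that("bm_loglik is invariant to rescaling the covariance", {
  tr <- simulate_tree(15, seed = 2)
  V <- vcv_from_tree(tr)
  x <- simulate_bm_trait(tr, seed = 3)
  base <- bm_loglik(x, V)
  for (c0 in c(0.1, 3, 40)) {
    scaled <- bm_loglik(x, c0 * V)
    expect_equal(scaled$loglik, base$loglik, tolerance = 1e-8)
    expect_equal(scaled$sigma2, base$sigma2 / c0, tolerance = 1e-8)
  }
})

test_that("a constant trait is flagged degenerate, not an error", {
  V <- vcv_from_tree(simulate_tree(8, seed = 4))
  x <- setNames(rep(3.2, 8), rownames(V))
  got <- bm_loglik(x, V)
  expect_true(got$degenerate)
  expect_equal(got$sigma2, 0)
})

test_that("lambda ML agrees with the phytools oracle", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(40, seed = 5)
  for (s in 6:8) {
    x <- simulate_bm_trait(tr, lambda_true = 0.6, seed = s)
    mine <- fit_lambda_ml(x, tr)
    ref <- phytools::phylosig(tr, x, method = "lambda")
    expect_equal(mine$lambda, ref$lambda, tolerance = 1e-3)
    expect_equal(mine$loglik, ref$logL, tolerance = 1e-5)
  }
})

test_that("lambda estimate attains the maximum of a dense likelihood grid", {
  tr <- simulate_tree(30, seed = 9)
  V <- vcv_from_tree(tr)
  for (s in c(10, 11)) {
    x <- simulate_bm_trait(tr, lambda_true = 0.8, seed = s)
    fit <- fit_lambda_ml(x, tr)
    grid <- seq(0, 1, length.out = 1001)
    ll <- vapply(grid, function(l)
      bm_loglik(x, lambda_transform(V, l))$loglik, numeric(1))
    expect_gte(fit$loglik, max(ll) - 1e-4)
    # invariant: at least as good as both boundaries
    expect_gte(fit$loglik, fit$loglik_lambda0 - 1e-6)
    expect_gte(fit$loglik, fit$loglik_lambda1 - 1e-6)
  }
})

test_that("lambda and K are invariant under affine trait transforms", {
  tr <- simulate_tree(25, seed = 12)
  x <- simulate_bm_trait(tr, seed = 13)
  f0 <- fit_lambda_ml(x, tr)
  k0 <- blomberg_k(x, tr)
  set.seed(14)
  for (i in 1:5) {
    a <- runif(1, -5, 5); if (abs(a) < 0.1) a <- 1
    b <- runif(1, -10, 10)
    expect_equal(fit_lambda_ml(a * x + b, tr)$lambda, f0$lambda,
                 tolerance = 1e-6)
    expect_equal(blomberg_k(a * x + b, tr), k0, tolerance = 1e-10)
  }
})

test_that("star trees force K = 1 for any trait", {
  tr <- star_tree(10)
  set.seed(15)
  for (i in 1:10) {
    x <- setNames(rnorm(10, sd = runif(1, 0.1, 10)), tr$tip.label)
    expect_equal(blomberg_k(x, tr), 1, tolerance = 1e-12)
  }
})

test_that("clade-structured traits on a deep two-clade tree give K > 1", {
  tr <- two_clade_tree(4)
  x <- setNames(c(rep(0, 4), rep(1, 4)), tr$tip.label)
  k <- blomberg_k(x, tr)
  expect_gt(k, 1)
  # brute-force evaluation of the defining formula with dense solves
  V <- vcv_from_tree(tr)
  x <- x[rownames(V)]
  n <- length(x)
  Vi <- solve(V)
  a <- drop(sum(Vi %*% x) / sum(Vi))
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- drop(t(x - a) %*% Vi %*% (x - a)) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  expect_equal(k, (mse0 / mse) / expected, tolerance = 1e-10)
})

test_that("K agrees with the phytools oracle on simulated traits", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(35, seed = 16)
  for (s in 17:19) {
    x <- simulate_bm_trait(tr, seed = s)
    expect_equal(blomberg_k(x, tr),
                 unclass(phytools::phylosig(tr, x, method = "K")),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("the K permutation test is deterministic given its seed", {
  tr <- simulate_tree(20, seed = 20)
  x <- simulate_bm_trait(tr, seed = 21)
  p1 <- k_permutation_test(x, tr, n_perm = 199, seed = 99)
  p2 <- k_permutation_test(x, tr, n_perm = 199, seed = 99)
  expect_identical(p1$p_perm, p2$p_perm)
  expect_gte(p1$p_perm, 1 / 200)
  expect_lte(p1$p_perm, 1)
  expect_error(k_permutation_test(x, tr, n_perm = 50, seed = 1), ">= 99")
  expect_error(k_permutation_test(x, tr, n_perm = 199), "seed")
})

test_that("an extreme clade-structured trait reaches the minimal p-value", {
  tr <- two_clade_tree(10, split = 0.99, tip = 0.01)
  set.seed(22)
  x <- setNames(c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01)), tr$tip.label)
  got <- k_permutation_test(x, tr, n_perm = 199, seed = 23)
  expect_equal(got$p_perm, 1 / 200)
})

test_that("the likelihood-ratio test matches chi-squared quantiles", {
  expect_equal(lr_test(-10, -10), 1)
  stat <- qchisq(0.95, df = 1)        # 3.841...
  expect_equal(lr_test(0, stat / 2), 0.05, tolerance = 1e-10)
  expect_equal(lr_test(0, stat / 2, boundary = TRUE), 0.025,
               tolerance = 1e-10)
  # round-off below the restricted fit is clamped, larger gaps error
  expect_equal(lr_test(-9.9999999, -10), 1)
  expect_error(lr_test(-5, -10), "optimizer failure")
})
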