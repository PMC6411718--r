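# Phylogenetic-signal statistics: profiled Brownian likelihood, ML Pagel's
# lambda, Blomberg's K, and a trait-permutation test. All linear algebra
# goes through a Cholesky factorization (log-determinants are never taken
# from a raw determinant); a 1e-10 diagonal jitter is added only when the
# factorization fails, with a warning.

.chol_factor <- function(V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    warning("covariance factorization failed; retrying with 1e-10 jitter ",
            "on the diagonal", call. = FALSE)
    R <- tryCatch(chol(V + diag(1e-10, nrow(V))), error = function(e)
      stop("singular phylogenetic covariance (condition too large even ",
           "after jitter)", call. = FALSE))
  }
  R
}

# whitened solve helper: returns z with z = R^-T x, so that
# crossprod of whitened vectors gives x' V^-1 y
.whiten <- function(R, x) backsolve(R, x, transpose = TRUE)

#' Profiled Brownian-motion log-likelihood of a trait on a tree
#'
#' For trait vector `x` with covariance proportional to `V`, profiles out the
#' root mean and rate: the GLS root state is
#' `a = (1' V^-1 1)^-1 1' V^-1 x`, the ML rate is
#' `sigma2 = (x - a)' V^-1 (x - a) / n`, and the log-likelihood is
#' `-(n/2) log(2 pi sigma2) - log|V|/2 - n/2`.
#'
#' @param x named numeric trait vector aligned to the rows of `V`.
#' @param V phylogenetic covariance matrix (possibly lambda-transformed),
#'   positive definite.
#' @return list with `loglik`, `root_mean`, `sigma2`, `degenerate` (TRUE if
#'   the trait is constant so `sigma2 = 0` and the likelihood is unbounded).
#' @export
bm_loglik <- function(x, V) {
  x <- .align_vec(x, V)
  n <- length(x)
  R <- .chol_factor(V)
  logdetV <- 2 * sum(log(diag(R)))
  z <- .whiten(R, x)
  u <- .whiten(R, rep(1, n))
  a <- sum(u * z) / sum(u * u)
  q <- sum((z - a * u)^2)          # (x - a 1)' V^-1 (x - a 1)
  sigma2 <- q / n
  scale <- max(sum(z^2), 1)
  if (sigma2 <= 1e-14 * scale / n) {
    return(list(loglik = Inf, root_mean = a, sigma2 = 0, degenerate = TRUE))
  }
  ll <- -(n / 2) * log(2 * pi * sigma2) - logdetV / 2 - n / 2
  list(loglik = ll, root_mean = a, sigma2 = sigma2, degenerate = FALSE)
}

.align_vec <- function(x, V) {
  if (!is.null(names(x)) && !is.null(rownames(V))) {
    if (!setequal(names(x), rownames(V))) {
      stop("trait names do not match covariance tip order; offenders: ",
           paste(c(setdiff(names(x), rownames(V)),
                   setdiff(rownames(V), names(x))), collapse = ", "),
           call. = FALSE)
    }
    x <- x[rownames(V)]
  }
  if (length(x) != nrow(V)) stop("trait length does not match covariance",
                                 call. = FALSE)
  if (any(!is.finite(x))) stop("missing or non-finite trait values",
                               call. = FALSE)
  x
}

# golden-section maximization of f on [lo, hi]; ties resolved leftward by
# strict-inequality updates
.golden_max <- function(f, lo, hi, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 >= f2) { b <- x2; x2 <- x1; f2 <- f1
                    x1 <- b - phi * (b - a); f1 <- f(x1) }
    else          { a <- x1; x1 <- x2; f1 <- f2
                    x2 <- a + phi * (b - a); f2 <- f(x2) }
  }
  xm <- (a + b) / 2
  list(x = xm, value = f(xm))
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximizes the profiled Brownian log-likelihood over the lambda transform
#' of the tree's covariance on [0, 1], using a 101-point grid followed by
#' golden-section refinement around the grid argmax (ties broken toward the
#' smaller lambda, convergence tolerance 1e-8 on lambda). Likelihood-ratio
#' tests against the two boundary hypotheses lambda = 0 (no phylogenetic
#' signal) and lambda = 1 (strict Brownian motion) are reported with the
#' boundary-corrected halved chi-squared(1) p-value.
#'
#' @param x named numeric trait vector.
#' @param tree an [ape::phylo] object (>= 4 tips); tip set must match
#'   `names(x)`.
#' @param grid_points number of coarse grid points on [0, 1].
#' @return object of class `"lambda_fit"`: list with `lambda`, `sigma2`,
#'   `root_mean`, `loglik`, `loglik_lambda0`, `loglik_lambda1`, `p_vs_zero`,
#'   `p_vs_one`, `degenerate`, `n`.
#' @export
fit_lambda_ml <- function(x, tree, grid_points = 101L) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 4L) stop("need >= 4 tips", call. = FALSE)
  V <- vcv_from_tree(tree)
  x <- .align_vec(x, V)
  if (stats::sd(x) == 0) {
    stop("constant trait: lambda is undefined", call. = FALSE)
  }
  prof <- function(lam) bm_loglik(x, lambda_transform(V, lam))$loglik

  grid <- seq(0, 1, length.out = grid_points)
  ll_grid <- vapply(grid, prof, numeric(1))
  degenerate <- FALSE
  if (max(ll_grid) - min(ll_grid) < 1e-10) {
    # flat profile (e.g. star tree: lambda does nothing); tie-break to 0
    lam_hat <- 0
    ll_hat <- ll_grid[1L]
    degenerate <- TRUE
  } else {
    i <- which.max(ll_grid)          # which.max takes the first (smaller) tie
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(grid_points, i + 1L)]
    ref <- .golden_max(prof, lo, hi)
    lam_hat <- ref$x
    ll_hat <- ref$value
    # the boundaries themselves are candidates the interior search can miss
    for (cand in c(0, 1)) {
      llc <- if (cand == 0) ll_grid[1L] else ll_grid[grid_points]
      if (llc > ll_hat + 1e-12 ||
          (abs(llc - ll_hat) <= 1e-12 && cand < lam_hat)) {
        lam_hat <- cand; ll_hat <- llc
      }
    }
    if (ll_grid[i] > ll_hat) { lam_hat <- grid[i]; ll_hat <- ll_grid[i] }
  }

  fit <- bm_loglik(x, lambda_transform(V, lam_hat))
  ll0 <- ll_grid[1L]
  ll1 <- ll_grid[grid_points]
  structure(list(lambda = lam_hat,
                 sigma2 = fit$sigma2,
                 root_mean = fit$root_mean,
                 loglik = ll_hat,
                 loglik_lambda0 = ll0,
                 loglik_lambda1 = ll1,
                 p_vs_zero = lr_test(ll0, ll_hat, boundary = TRUE),
                 p_vs_one  = lr_test(ll1, ll_hat, boundary = TRUE),
                 degenerate = degenerate,
                 n = length(x)),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda (ML)\n")
  cat(sprintf("  lambda = %.6g   sigma2 = %.6g   logLik = %.4f\n",
              x$lambda, x$sigma2, x$loglik))
  cat(sprintf("  LR test vs lambda = 0: p = %.4g\n", x$p_vs_zero))
  cat(sprintf("  LR test vs lambda = 1: p = %.4g\n", x$p_vs_one))
  if (x$degenerate) cat("  note: flat likelihood profile\n")
  invisible(x)
}

#' Boundary-aware likelihood-ratio test
#'
#' Computes `Lambda = 2 * (loglik_full - loglik_restricted)` and returns the
#' chi-squared(1) upper-tail p-value. When the restricted value lies on the
#' boundary of the parameter space the null distribution is the 50:50
#' mixture of a point mass at 0 and chi-squared(1), so the p-value is
#' halved. Small negative `Lambda` within tolerance is clamped to 0.
#'
#' @param loglik_restricted,loglik_full log-likelihoods of the nested fits.
#' @param boundary is the restricted parameter on the boundary?
#' @param tol tolerance for optimizer round-off.
#' @return two-sided p-value in (0, 1].
#' @export
lr_test <- function(loglik_restricted, loglik_full, boundary = FALSE,
                    tol = 1e-6) {
  stat <- 2 * (loglik_full - loglik_restricted)
  if (stat < -tol) {
    stop("optimizer failure: full log-likelihood below restricted by ",
         format(-stat), call. = FALSE)
  }
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary) p <- p / 2
  min(p, 1)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the observed ratio of trait mean squared error to its GLS
#' (phylogenetically corrected) counterpart with the ratio expected under
#' Brownian motion:
#' `K = (MSE0 / MSE) / E_BM`, where with `a` the GLS mean,
#' `MSE0 = (x - a)'(x - a) / (n - 1)`,
#' `MSE = (x - a)' V^-1 (x - a) / (n - 1)`, and
#' `E_BM = (tr(V) - n / sum(V^-1)) / (n - 1)`.
#' K = 1 under Brownian motion on the given tree; K < 1 means relatives
#' resemble each other less than Brownian motion predicts (variation sits
#' within subgroups), K > 1 more.
#'
#' @param x named numeric trait vector.
#' @param tree an [ape::phylo] object (>= 4 tips).
#' @return the K value (non-negative scalar).
#' @export
blomberg_k <- function(x, tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 4L) stop("need >= 4 tips", call. = FALSE)
  V <- vcv_from_tree(tree)
  x <- .align_vec(x, V)
  if (stats::sd(x) == 0) stop("constant trait: K is undefined",
                              call. = FALSE)
  n <- length(x)
  R <- .chol_factor(V)
  z <- .whiten(R, x)
  u <- .whiten(R, rep(1, n))
  one_Vi_one <- sum(u * u)
  a <- sum(u * z) / one_Vi_one
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- sum((z - a * u)^2) / (n - 1)
  expected <- (sum(diag(V)) - n / one_Vi_one) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for phylogenetic signal under Blomberg's framework
#'
#' Shuffles trait values across the tips and compares the observed GLS mean
#' squared error with its permutation distribution; a small observed MSE
#' (relatives more similar than random) is evidence of signal. The p-value
#' uses the add-one estimator
#' `p = (1 + #\{MSE_perm <= MSE_obs\}) / (n_perm + 1)` and is deterministic
#' given `seed`.
#'
#' @param x named numeric trait vector.
#' @param tree an [ape::phylo] object.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed (mandatory, recorded in the result).
#' @return object of class `"k_result"`: list with `k`, `p_perm`, `n_perm`,
#'   `seed`, `mse_observed`.
#' @export
k_permutation_test <- function(x, tree, n_perm = 999L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  validate_phylogeny(tree)
  V <- vcv_from_tree(tree)
  x <- .align_vec(x, V)
  if (stats::sd(x) == 0) stop("constant trait: K is undefined",
                              call. = FALSE)
  n <- length(x)
  R <- .chol_factor(V)
  Vi <- chol2inv(R)
  vi1 <- rowSums(Vi)
  s11 <- sum(vi1)
  gls_mse <- function(xx) {
    w <- Vi %*% xx
    (sum(xx * w) - sum(vi1 * xx)^2 / s11) / (n - 1)
  }
  obs <- gls_mse(x)
  set.seed(as.integer(seed))
  perm_mse <- vapply(seq_len(n_perm),
                     function(i) gls_mse(x[sample.int(n)]),
                     numeric(1))
  p <- (1 + sum(perm_mse <= obs)) / (n_perm + 1)
  structure(list(k = blomberg_k(x, tree),
                 p_perm = p,
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 mse_observed = obs),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat("Blomberg's K with permutation test\n")
  cat(sprintf("  K = %.4f   p = %.4g  (%d permutations, seed %d)\n",
              x$k, x$p_perm, x$n_perm, x$seed))
  invisible(x)
}
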