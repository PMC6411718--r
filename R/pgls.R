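#' Phylogenetic generalized least squares regression
#'
#' Regression of a continuous species trait (e.g. the EF ratio) on one or
#' more predictors (e.g. 0/1 wing-pigmentation or light-courtship columns)
#' with error covariance proportional to the phylogenetic covariance `V`.
#' Two correlation modes are supported: `"brownian"` fixes the error
#' structure at the strict Brownian `V`; `"ml_lambda"` (the default, matching
#' the common practice of re-estimating the transform per regression)
#' replaces `V` with its Pagel-lambda transform at the lambda that maximizes
#' the regression's profiled log-likelihood over [0, 1].
#'
#' Coefficients are `beta = (X' V*^-1 X)^-1 X' V*^-1 y` with residual
#' variance `sigma2 = (y - X beta)' V*^-1 (y - X beta) / (n - p)`, standard
#' errors from `sigma2 (X' V*^-1 X)^-1`, and two-sided t p-values on `n - p`
#' degrees of freedom. With the identity covariance the fit reduces exactly
#' to ordinary least squares.
#'
#' @param y named numeric response vector.
#' @param X design matrix including an intercept column, rows aligned to the
#'   tree tips (rownames used for alignment when present).
#' @param tree an [ape::phylo] object whose tip set matches `names(y)`.
#' @param mode `"ml_lambda"` (default) or `"brownian"`.
#' @return object of class `"pgls_fit"`: list with `coefficients`,
#'   `standard_errors`, `t_values`, `p_values`, `correlation_mode`,
#'   `lambda_used`, `sigma2`, `df`, `loglik`, `residuals`, `fitted`, `n`.
#' @export
pgls_fit <- function(y, X, tree, mode = c("ml_lambda", "brownian")) {
  mode <- match.arg(mode)
  validate_phylogeny(tree)
  V <- vcv_from_tree(tree)
  y <- .align_vec(y, V)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) {
    stop("design matrix rows do not match response length", call. = FALSE)
  }
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), rownames(V))) {
      stop("design matrix tips do not match tree; offenders: ",
           paste(c(setdiff(rownames(X), rownames(V)),
                   setdiff(rownames(V), rownames(X))), collapse = ", "),
           call. = FALSE)
    }
    X <- X[rownames(V), , drop = FALSE]
  }
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (qr(X)$rank < p) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(y)
  if (n <= p) stop("need more species than coefficients", call. = FALSE)

  gls_at <- function(W) {
    R <- .chol_factor(W)
    ty <- .whiten(R, y)
    tX <- .whiten(R, X)
    fit <- stats::lm.fit(tX, ty)
    rss <- sum(fit$residuals^2)
    logdet <- 2 * sum(log(diag(R)))
    ll <- -(n / 2) * log(2 * pi * rss / n) - logdet / 2 - n / 2
    list(R = R, fit = fit, rss = rss, loglik = ll)
  }

  lambda_used <- 1
  if (mode == "ml_lambda") {
    prof <- function(lam) gls_at(lambda_transform(V, lam))$loglik
    grid <- seq(0, 1, length.out = 101L)
    llg <- vapply(grid, prof, numeric(1))
    i <- which.max(llg)
    ref <- .golden_max(prof, grid[max(1L, i - 1L)], grid[min(101L, i + 1L)])
    cand <- c(ref$x, grid[i], 0, 1)
    cll <- c(ref$value, llg[i], llg[1L], llg[101L])
    best <- order(-cll, cand)[1L]   # max loglik, ties toward smaller lambda
    lambda_used <- cand[best]
  }

  W <- lambda_transform(V, lambda_used)
  g <- gls_at(W)
  beta <- stats::setNames(unname(g$fit$coefficients), colnames(X))
  df <- n - p
  sigma2 <- g$rss / df
  tX <- .whiten(g$R, X)
  XtXinv <- chol2inv(qr.R(qr(tX)))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  tv <- beta / se
  fitted <- drop(X %*% beta)
  structure(list(coefficients = beta,
                 standard_errors = se,
                 t_values = tv,
                 p_values = 2 * stats::pt(-abs(tv), df),
                 correlation_mode = mode,
                 lambda_used = lambda_used,
                 sigma2 = sigma2,
                 df = df,
                 loglik = g$loglik,
                 residuals = y - fitted,
                 fitted = fitted,
                 n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic generalized least squares (", x$correlation_mode,
      ", lambda = ", format(x$lambda_used, digits = 4), ")\n", sep = "")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$standard_errors,
               `t value` = x$t_values, `Pr(>|t|)` = x$p_values)
  stats::printCoefmat(tab, digits = 4)
  cat(sprintf("  residual sigma2 = %.4g on %d df\n", x$sigma2, x$df))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' Confidence intervals for PGLS coefficients
#' @param object a `pgls_fit`.
#' @param parm coefficients to include (names or indices; default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.pgls_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  tq <- stats::qt(1 - (1 - level) / 2, object$df)
  ci <- cbind(cf - tq * object$standard_errors,
              cf + tq * object$standard_errors)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2,
                                       1 - (1 - level) / 2)), "%")
  ci[parm, , drop = FALSE]
}
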