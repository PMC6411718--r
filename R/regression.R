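#' Log-log allometric regression with an isometry test
#'
#' Fits ordinary least squares of `log(trait)` on `log(size)` and tests the
#' slope against the isometric expectation: 2 for an area regressed on a
#' linear size measure, 1 for a length on a length. A slope consistent with
#' the expectation means the trait scales isometrically with body/head size.
#'
#' @param size vector of linear size measurements (micrometres, > 0).
#' @param trait vector of trait values (micrometres or square micrometres,
#'   > 0), same length as `size`.
#' @param expected_slope isometric reference slope (2 for area-vs-length,
#'   1 for length-vs-length).
#' @param conf_level confidence level for the slope interval.
#' @return an object of class `"allometry_fit"`: list with `slope`,
#'   `intercept`, `slope_se`, `slope_ci`, `expected_slope`, `p_isometry`
#'   (two-sided t test of slope = expected), `r_squared`, `df`, `n`.
#' @export
allometry_fit <- function(size, trait, expected_slope, conf_level = 0.95) {
  if (length(size) != length(trait)) {
    stop("size and trait must have equal length", call. = FALSE)
  }
  if (length(size) < 3L) {
    stop("allometry fit needs at least 3 points", call. = FALSE)
  }
  .check_positive(size = size, trait = trait)
  fit <- stats::lm(log(trait) ~ log(size))
  sm <- summary(fit)
  b <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  df <- fit$df.residual
  tstat <- (b - expected_slope) / se
  ci <- unname(stats::confint(fit, level = conf_level)[2L, ])
  structure(list(slope = b,
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_se = se,
                 slope_ci = ci,
                 expected_slope = expected_slope,
                 p_isometry = 2 * stats::pt(-abs(tstat), df),
                 r_squared = sm$r.squared,
                 df = df,
                 n = length(size)),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Allometric log-log regression (n =", x$n, ")\n")
  cat(sprintf("  slope     %.4f  (SE %.4f, %s CI %.4f..%.4f)\n",
              x$slope, x$slope_se, "95%", x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4f   R^2 %.4f\n", x$intercept, x$r_squared))
  cat(sprintf("  isometry test vs slope %g: p = %.4g\n",
              x$expected_slope, x$p_isometry))
  invisible(x)
}

#' Multiple linear regression with named-column rank diagnostics
#'
#' Ordinary least squares of a response on a predictor matrix that already
#' contains an intercept column, with `n - p` residual degrees of freedom.
#' Rank-deficient designs are rejected with an error naming the collinear
#' columns rather than silently dropping them.
#'
#' @param response numeric response vector.
#' @param predictors numeric matrix including an intercept column; column
#'   names are used in output and error messages.
#' @return list with `coefficients`, `standard_errors`, `t_values`,
#'   `p_values` (all named by column), `df`, `sigma2` (residual variance),
#'   `residuals`, `fitted`.
#' @export
multiple_regression <- function(response, predictors) {
  X <- as.matrix(predictors)
  y <- as.numeric(response)
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("response/predictor row mismatch", call. = FALSE)
  if (n < p + 1L) {
    stop("need at least ncol(predictors) + 1 observations", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  tv <- beta / se
  list(coefficients = beta,
       standard_errors = se,
       t_values = tv,
       p_values = 2 * stats::pt(-abs(tv), df),
       df = df,
       sigma2 = sigma2,
       residuals = res,
       fitted = drop(X %*% beta))
}

#' Pearson correlation between two trait vectors
#'
#' Product-moment correlation with the usual t-based two-sided p-value on
#' `n - 2` degrees of freedom, e.g. for relating larval disc ratios to adult
#' EF ratios across species.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
trait_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("equal length required", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(x))
}
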