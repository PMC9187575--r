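#' Ordinary least squares fit with classical or sandwich standard errors
#'
#' Fits the linear model `y = alpha + X beta + e` by least squares. Standard
#' errors are either the classical homoskedastic form
#' `sigma2_hat * (X'X)^-1` or the HC1 heteroskedasticity-consistent sandwich
#' estimator (degrees-of-freedom scaled), which remains valid when the error
#' variance depends on the predictors.
#'
#' @param y Numeric outcome vector.
#' @param X Predictors: vector, matrix or data frame (see [build_design()]).
#'   The intercept is added internally; do not supply one.
#' @param cov_type `"classical"` or `"sandwich"` (HC1).
#' @return An object of class `ols_fit`: a list with `intercept`, `slopes`,
#'   `residuals`, `fitted`, `sigma2_hat`, `standard_errors` (slopes only),
#'   `vcov` (slopes block), `cov_type`, `n`, `p`.
#' @examples
#' fit <- fit_ols(c(2, 4, 6, 8), c(1, 2, 3, 4))
#' fit$slopes
#' @seealso [location_test()], [residualize()]
#' @export
fit_ols <- function(y, X, cov_type = c("classical", "sandwich")) {
  cov_type <- match.arg(cov_type)
  X <- build_design(X, name = deparse(substitute(X)))
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    abort("length(y) must equal nrow(X)", class = "jointvar_data_error")
  }
  if (any(!is.finite(y))) {
    abort("y contains non-finite values", class = "jointvar_data_error")
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) {
    abort("too few observations for the number of predictors",
      class = "jointvar_data_error"
    )
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  coefs <- qr.coef(qr_x, y)
  fitted <- drop(Xi %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  df_res <- n - p - 1
  sigma2 <- rss / df_res
  XtX_inv <- chol2inv(qr.R(qr_x))
  if (cov_type == "classical") {
    V <- sigma2 * XtX_inv
  } else {
    # HC1: (X'X)^-1 X' diag(e^2) X (X'X)^-1 * n/(n - p - 1)
    meat <- crossprod(Xi * res)
    V <- XtX_inv %*% meat %*% XtX_inv * n / df_res
  }
  dimnames(V) <- list(colnames(Xi), colnames(Xi))
  structure(
    list(
      intercept = unname(coefs[1]),
      slopes = coefs[-1],
      residuals = res,
      fitted = fitted,
      sigma2_hat = sigma2,
      standard_errors = sqrt(diag(V))[-1],
      vcov = V,
      cov_type = cov_type,
      n = n,
      p = p
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit (", x$cov_type, " covariance): n = ", x$n,
    ", p = ", x$p, "\n",
    sep = ""
  )
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_ols
#' @param x An `ols_fit` object.
#' @param ... Unused.
#' @export
tidy.ols_fit <- function(x, ...) {
  est <- c(x$intercept, x$slopes)
  se <- sqrt(diag(x$vcov))
  z <- est / se
  tibble(
    term = c("(Intercept)", names(x$slopes)),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
}

#' @rdname fit_ols
#' @export
glance.ols_fit <- function(x, ...) {
  tibble(
    sigma2_hat = x$sigma2_hat,
    nobs = x$n,
    df.residual = x$n - x$p - 1,
    cov_type = x$cov_type
  )
}

#' Residualize a vector or matrix on a set of adjustment variables
#'
#' Removes the linear effect of covariates `C` (with intercept) from `v` by
#' OLS projection, returning the residuals. Used to adjust both outcome and
#' exposure for nuisance variables before a joint score test. The output is
#' numerically orthogonal to the columns of `C` and mean-centered.
#'
#' @param v Numeric vector or matrix (columns residualized independently).
#' @param C Covariates: vector, matrix or data frame.
#' @return Object of the same shape as `v`.
#' @examples
#' z <- rnorm(20)
#' r <- residualize(rnorm(20), z)
#' abs(sum(r * z)) < 1e-8
#' @export
residualize <- function(v, C) {
  C <- build_design(C, name = deparse(substitute(C)))
  vm <- as.matrix(v)
  if (nrow(vm) != nrow(C)) {
    abort("v and C must have the same number of rows",
      class = "jointvar_data_error"
    )
  }
  Ci <- cbind(1, C)
  res <- qr.resid(qr(Ci), vm)
  if (is.matrix(v)) {
    dimnames(res) <- dimnames(v)
    res
  } else {
    drop(res)
  }
}
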