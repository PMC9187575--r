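#' Joint location-and-scale score test (JLSsc)
#'
#' A single score test of the joint null of no mean effect and no variance
#' effect of the exposure on the outcome. It stacks the linear mean model
#' with a Breusch-Pagan-style auxiliary regression of the squared centered
#' outcome on the exposure, with the mean restriction imposed under the
#' null (the auxiliary variable is `(y_i - mean(y))^2`, not a squared OLS
#' residual, which enhances power). The two coefficient vectors are
#' estimated by OLS on the centered data and combined in a quadratic form
#' with a Kronecker-structured null covariance; under the null the
#' statistic is asymptotically chi-squared with `2 * k_x` degrees of
#' freedom, where `k_x` is the number of exposure columns.
#'
#' The default covariance estimator assumes the conditional skewness and
#' kurtosis of the outcome do not depend on the exposure (automatic under
#' normality). `robust = TRUE` replaces it with a stacked
#' estimating-equation sandwich built from per-observation outer products,
#' dropping that assumption at some cost in power.
#'
#' Covariates are removed from both the outcome and every exposure column
#' by linear residualization before the test. With `include_square = TRUE`
#' the squares of the centered exposure columns are appended, doubling the
#' degrees of freedom; this targets variance effects that are nonlinear in
#' a continuous exposure. Outlier removal (`outlier_sd`) trims observations
#' whose outcome lies more than that many standard deviations from the
#' mean before testing; it is recommended for categorical exposures with
#' small groups and for squared-term designs, where extreme outcome values
#' otherwise inflate the test.
#'
#' @inheritParams location_test
#' @param include_square Append squared centered exposure columns.
#' @param robust Use the skewness/kurtosis-robust sandwich covariance.
#' @param outlier_sd Optional positive number: remove observations with
#'   outcome further than this many SDs from the mean before testing.
#' @return One-row tibble with `method`, `statistic`, `df = 2 * k_x`,
#'   `p_value`, `n_used` and `n_outliers_removed`. The full set of
#'   intermediates (centered data, `beta_hat`, `delta_hat`, `Sigma_hat`,
#'   ...) is attached as attribute `"state"`.
#' @examples
#' d <- data.frame(x = rbinom(200, 1, 0.5))
#' d$y <- rnorm(200, mean = 0.2 * d$x, sd = 1 + 0.3 * d$x)
#' jlssc(d, "y", "x")
#' @export
jlssc <- function(data, outcome, exposure, covariates = NULL,
                  include_square = FALSE, robust = FALSE,
                  outlier_sd = NULL) {
  md <- extract_model_data(data, outcome, exposure, covariates)
  y <- md$y
  X <- md$X
  C <- md$C
  n_out <- 0L
  if (!is.null(outlier_sd)) {
    mask <- remove_outliers(y, threshold_sd = outlier_sd)
    n_out <- mask$n_removed
    if (n_out > 0) {
      y <- y[mask$keep]
      X <- check_design(X[mask$keep, , drop = FALSE])
      C <- if (!is.null(C)) check_design(C[mask$keep, , drop = FALSE])
    }
  }
  res <- jlssc_fit(y, X, C,
    include_square = include_square, robust = robust
  )
  out <- tibble(
    method = if (robust) "jlssc_robust" else "jlssc",
    statistic = res$statistic, df = res$df, p_value = res$p_value,
    n_used = length(y), n_outliers_removed = n_out
  )
  attr(out, "state") <- res$state
  out
}

# Core of the score test; y numeric, X design matrix, C optional design.
jlssc_fit <- function(y, X, C = NULL, include_square = FALSE,
                      robust = FALSE) {
  n <- length(y)
  if (!is.null(C)) {
    y <- residualize(y, C)
    X <- residualize(unclass(X), C)
  }
  y_c <- y - mean(y)
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  if (include_square) {
    sq <- Xc^2
    colnames(sq) <- paste0(colnames(Xc) %||% paste0("x", seq_len(ncol(Xc))), "_sq")
    Xc <- cbind(Xc, sweep(sq, 2, colMeans(sq)))
  }
  kx <- ncol(Xc)
  if (n <= 2 * kx + 5) {
    abort("too few observations for the joint score test",
      class = "jointvar_data_error"
    )
  }
  sigma2 <- mean(y_c^2)
  if (sigma2 <= 0) {
    abort("degenerate outcome: zero variance", class = "jointvar_degenerate_error")
  }
  d_c <- y_c^2 - sigma2
  XtX <- crossprod(Xc)
  qr_x <- qr(XtX)
  if (qr_x$rank < kx) {
    abort("exposure design is rank deficient after centering",
      class = "jointvar_design_error"
    )
  }
  beta_hat <- solve(qr_x, crossprod(Xc, y_c))
  delta_hat <- solve(qr_x, crossprod(Xc, d_c))
  Sigma <- matrix(
    c(
      mean(y_c^2), mean(y_c * d_c),
      mean(y_c * d_c), mean(d_c^2)
    ),
    2, 2
  )
  theta <- c(beta_hat, delta_hat)
  if (!robust) {
    if (kappa(Sigma) > 1e12 || any(diag(Sigma) <= 0)) {
      abort("degenerate moment matrix", class = "jointvar_degenerate_error")
    }
    Sigma_inv <- solve(Sigma)
    # S = theta' (Sigma^-1 (x) X'X) theta, expanded over the 2x2 blocks
    Bb <- drop(crossprod(beta_hat, XtX %*% beta_hat))
    Bd <- drop(crossprod(beta_hat, XtX %*% delta_hat))
    Dd <- drop(crossprod(delta_hat, XtX %*% delta_hat))
    S <- Sigma_inv[1, 1] * Bb + 2 * Sigma_inv[1, 2] * Bd + Sigma_inv[2, 2] * Dd
  } else {
    # stacked estimating-equation sandwich: g_i = (x_i y_i, x_i d_i)
    G <- cbind(Xc * y_c, Xc * d_c)
    B <- crossprod(G)
    XtX_inv <- solve(qr_x, diag(kx))
    A <- kronecker(diag(2), XtX_inv)
    V <- A %*% B %*% A
    if (kappa(V) > 1e12) {
      abort("degenerate moment matrix", class = "jointvar_degenerate_error")
    }
    S <- drop(crossprod(theta, solve(V, theta)))
  }
  df <- 2L * kx
  list(
    statistic = S, df = df,
    p_value = p_floor(pchisq(S, df = df, lower.tail = FALSE)),
    state = list(
      y_centered = y_c, X_centered = Xc, sigma2_hat = sigma2,
      d_centered = d_c, beta_hat = drop(beta_hat),
      delta_hat = drop(delta_hat), theta_hat = theta,
      Sigma_hat = Sigma, S = S, kx = kx, robust = robust,
      assumes_constant_skew_kurtosis = !robust
    )
  )
}

#' Joint location-and-scale test by Fisher combination (JLSp)
#'
#' Combines the location-test p-value (joint Wald over the exposure
#' columns) with the extended Brown-Forsythe scale-test p-value using
#' Fisher's method: `-2 * (log p1 + log p2)` referred to chi-squared with 4
#' degrees of freedom. Valid when the two p-values are independent, which
#' holds for symmetrically distributed outcomes; for skewed outcomes the
#' mean and variance estimates are correlated and the combination shows
#' some type-I-error inflation (the score test [jlssc()] does not).
#'
#' @inheritParams location_test
#' @return One-row tibble with `method`, `statistic`, `df = 4`, `p_value`,
#'   the component p-values `p_location` and `p_scale`, and `n_used`.
#' @examples
#' d <- data.frame(x = rnorm(100), y = rnorm(100))
#' jlsp(d, "y", "x")
#' @export
jlsp <- function(data, outcome, exposure, covariates = NULL) {
  md <- extract_model_data(data, outcome, exposure, covariates)
  res <- jlsp_fit(md$y, md$X, md$C)
  tibble(
    method = "jlsp",
    statistic = res$statistic, df = 4L, p_value = res$p_value,
    p_location = res$p_location, p_scale = res$p_scale, n_used = md$n
  )
}

jlsp_fit <- function(y, X, C = NULL) {
  p1 <- location_test_fit(y, X, C, cov_type = "classical")$p_value
  p2 <- bf_extended_fit(y, X, C)$p_value
  fc <- fisher_combine(c(p1, p2))
  list(
    statistic = fc$statistic, p_value = fc$p_value,
    p_location = p1, p_scale = p2
  )
}

#' Combine independent p-values with Fisher's method
#'
#' @param p Vector of p-values in (0, 1].
#' @return List with `statistic = -2 * sum(log(p))`, `df = 2 * length(p)`
#'   and the upper-tail chi-squared `p_value`.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0 || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]", class = "jointvar_data_error")
  }
  stat <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(
    statistic = stat, df = df,
    p_value = p_floor(pchisq(stat, df = df, lower.tail = FALSE))
  )
}
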