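#' Location (mean-effect) test by linear regression
#'
#' Tests whether the exposure shifts the mean of the outcome by fitting
#' `outcome = alpha + exposure * beta + covariates * gamma + e` with OLS and
#' applying a z-test per exposure coefficient plus a joint Wald chi-squared
#' test across all exposure columns. With `cov_type = "sandwich"` the Wald
#' statistic uses HC1 heteroskedasticity-consistent standard errors, which
#' keeps the test calibrated when the outcome variance depends on the
#' exposure.
#'
#' @param data A data frame with one row per sample.
#' @param outcome Name of the numeric outcome column.
#' @param exposure Name(s) of the exposure column(s). Factor or character
#'   columns are expanded to indicator contrasts.
#' @param covariates Optional name(s) of adjustment columns, entered as
#'   additional regression columns.
#' @param cov_type `"classical"` or `"sandwich"` (HC1).
#' @return A one-row tibble with the joint Wald `statistic`, `df`,
#'   `p_value`, the estimate and standard error of the first exposure
#'   column (`estimate`, `std_error`, `p_coef`), `n_used` and `method`. The
#'   full per-coefficient table is attached as attribute `"coefficients"`.
#' @examples
#' d <- data.frame(y = rnorm(50), x = rnorm(50))
#' location_test(d, "y", "x")
#' @export
location_test <- function(data, outcome, exposure, covariates = NULL,
                          cov_type = c("classical", "sandwich")) {
  cov_type <- match.arg(cov_type)
  md <- extract_model_data(data, outcome, exposure, covariates)
  res <- location_test_fit(md$y, md$X, md$C, cov_type)
  out <- tibble(
    method = paste0("ols_", cov_type),
    statistic = res$statistic,
    df = res$df,
    p_value = res$p_value,
    estimate = res$estimate,
    std_error = res$std_error,
    p_coef = res$p_coef,
    n_used = md$n
  )
  attr(out, "coefficients") <- res$coefficients
  out
}

# Vector-level location test used by the simulation registry and the scan.
location_test_fit <- function(y, X, C = NULL, cov_type = "classical") {
  X <- build_design(X, name = "exposure")
  q <- ncol(X)
  full <- if (is.null(C)) X else cbind(X, C)
  fit <- fit_ols(y, full, cov_type = cov_type)
  V <- fit$vcov[1 + seq_len(q), 1 + seq_len(q), drop = FALSE]
  b <- fit$slopes[seq_len(q)]
  stat <- drop(crossprod(b, solve(V, b)))
  se <- fit$standard_errors[seq_len(q)]
  z <- b / se
  list(
    statistic = stat,
    df = q,
    p_value = p_floor(pchisq(stat, df = q, lower.tail = FALSE)),
    estimate = unname(b[1]),
    std_error = unname(se[1]),
    p_coef = p_floor(2 * pnorm(-abs(unname(z[1])))),
    coefficients = tibble(
      term = names(b),
      estimate = unname(b),
      std.error = unname(se),
      statistic = unname(z),
      p.value = 2 * pnorm(-abs(unname(z)))
    ),
    fit = fit
  )
}
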