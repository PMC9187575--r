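#' M-value transform of methylation beta values
#'
#' Elementwise `log2(y / (1 - y))`, the standard variance-stabilizing
#' transform of methylation proportions. Strictly increasing on (0, 1).
#' Values at or outside the unit interval are an error — no silent
#' clipping.
#'
#' @param y Numeric vector with all values strictly inside (0, 1).
#' @return Numeric vector of M-values.
#' @examples
#' m_value(c(0.5, 0.8))
#' @export
m_value <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || any(y <= 0) || any(y >= 1)) {
    abort("all values must lie strictly inside (0, 1)",
      class = "jointvar_data_error"
    )
  }
  log2(y / (1 - y))
}

#' Inverse-normal rank transform
#'
#' Maps values to normal quantiles of their ranks using the Blom offset:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties. The
#' result is order-preserving with sample mean approximately zero. Forcing
#' marginal normality this way restores calibration of normality-dependent
#' variance tests on skewed data, but a genuine mean effect can be
#' converted into an apparent variability effect (and vice versa), so
#' mean/variance attribution after transformation needs care.
#'
#' @param y Numeric vector, length at least 2, not all values identical.
#' @return Numeric vector of normal scores.
#' @examples
#' inverse_normal_rank(c(3, 1, 2))
#' @export
inverse_normal_rank <- function(y) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2) {
    abort("need at least 2 observations", class = "jointvar_data_error")
  }
  if (anyNA(y)) {
    abort("missing values not allowed", class = "jointvar_data_error")
  }
  if (length(unique(y)) == 1) {
    abort("all values identical; ranks are uninformative",
      class = "jointvar_degenerate_error"
    )
  }
  r <- rank(y, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Flag outcome outliers beyond a standard-deviation threshold
#'
#' Single-pass rule: flags observations with
#' `|y - mean(y)| > threshold_sd * sd(y)`. No re-iteration after removal.
#'
#' @param y Numeric vector, length at least 3.
#' @param threshold_sd Positive threshold in SD units (default 3).
#' @return An `outlier_mask`: list with logical `keep`, `threshold_sd` and
#'   `n_removed`.
#' @examples
#' remove_outliers(c(rnorm(50), 40))
#' @export
remove_outliers <- function(y, threshold_sd = 3) {
  y <- as.numeric(y)
  if (length(y) < 3) {
    abort("need at least 3 observations", class = "jointvar_data_error")
  }
  if (anyNA(y)) {
    abort("missing values not allowed", class = "jointvar_data_error")
  }
  stopifnot(is.numeric(threshold_sd), threshold_sd > 0)
  s <- stats::sd(y)
  if (s == 0) {
    abort("zero standard deviation; outlier rule undefined",
      class = "jointvar_degenerate_error"
    )
  }
  keep <- abs(y - mean(y)) <= threshold_sd * s
  structure(
    list(keep = keep, threshold_sd = threshold_sd, n_removed = sum(!keep)),
    class = "outlier_mask"
  )
}

#' @export
print.outlier_mask <- function(x, ...) {
  cat(
    "outlier mask: ", x$n_removed, " of ", length(x$keep),
    " removed at ", x$threshold_sd, " SD\n",
    sep = ""
  )
  invisible(x)
}
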