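#' Bartlett's test of equal variances across groups
#'
#' Classical chi-squared test of variance homogeneity for a continuous
#' outcome across the levels of a categorical exposure. Powerful under
#' normality but highly sensitive to heavy tails, skewness and outliers —
#' on non-normal data it behaves as a test of non-normality rather than of
#' variance heterogeneity, which is why the Brown-Forsythe family is
#' preferred for phenotypes such as DNA methylation.
#'
#' @param data A data frame with one row per sample.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the grouping (categorical exposure) column.
#' @return One-row tibble with `method`, `statistic`, `df1`, `df2` (`NA`,
#'   chi-squared reference), `p_value`, `k` groups and `n_used`.
#' @examples
#' d <- data.frame(y = rnorm(40), g = rep(c("a", "b"), 20))
#' bartlett_test(d, "y", "g")
#' @export
bartlett_test <- function(data, outcome, group) {
  md <- grouped_data(data, outcome, group)
  res <- bartlett_fit(md$y, md$g)
  tibble(
    method = "bartlett",
    statistic = res$statistic, df1 = res$df1, df2 = NA_integer_,
    p_value = res$p_value, k = res$k, n_used = length(md$y)
  )
}

bartlett_fit <- function(y, g) {
  check_groups(y, g)
  vars <- tapply(y, g, stats::var)
  if (any(vars == 0)) {
    abort("a group has zero variance; Bartlett's statistic is undefined",
      class = "jointvar_degenerate_error"
    )
  }
  bt <- stats::bartlett.test(y, g)
  k <- length(vars)
  list(
    statistic = unname(bt$statistic), df1 = k - 1L, k = k,
    p_value = p_floor(unname(bt$p.value))
  )
}

#' Brown-Forsythe test of variance heterogeneity (categorical exposure)
#'
#' Levene-type test using absolute deviations from group medians,
#' `z_ij = |y_ij - median_j|`, followed by a one-way analysis of variance of
#' the `z_ij`. Under the null of equal group variances the statistic is
#' F-distributed with `k - 1` and `n - k` degrees of freedom. Robust to
#' non-normality and outliers.
#'
#' @inheritParams bartlett_test
#' @return One-row tibble with `method`, `statistic`, `df1 = k - 1`,
#'   `df2 = n - k`, `p_value`, `k` and `n_used`.
#' @examples
#' d <- data.frame(y = c(rnorm(30), rnorm(30, sd = 2)), g = rep(0:1, each = 30))
#' brown_forsythe(d, "y", "g")
#' @export
brown_forsythe <- function(data, outcome, group) {
  md <- grouped_data(data, outcome, group)
  res <- bf_classic_fit(md$y, md$g)
  tibble(
    method = "brown_forsythe",
    statistic = res$statistic, df1 = res$df1, df2 = res$df2,
    p_value = res$p_value, k = res$k, n_used = length(md$y)
  )
}

bf_classic_fit <- function(y, g) {
  check_groups(y, g)
  g <- as.factor(g)
  n <- length(y)
  k <- nlevels(g)
  med <- tapply(y, g, stats::median)
  z <- abs(y - med[g])
  zbar_j <- tapply(z, g, mean)
  n_j <- tabulate(g)
  zbar <- mean(z)
  num <- (n - k) * sum(n_j * (zbar_j[levels(g)] - zbar)^2)
  den <- (k - 1) * sum((z - zbar_j[g])^2)
  if (den <= 0) {
    if (num == 0) {
      # all spreads identical and constant: conventionally no evidence
      abort("all within-group deviations are constant; statistic undefined",
        class = "jointvar_degenerate_error"
      )
    }
    abort("zero within-group variation of |y - median|; statistic undefined",
      class = "jointvar_degenerate_error"
    )
  }
  stat <- num / den
  list(
    statistic = stat, df1 = k - 1L, df2 = n - k, k = k,
    p_value = p_floor(pf(stat, k - 1, n - k, lower.tail = FALSE))
  )
}

#' Extended Brown-Forsythe test for arbitrary exposures
#'
#' Regression reformulation of the Brown-Forsythe test that also covers
#' continuous (and mixed) exposures: (i) fit a least absolute deviation
#' regression of the outcome on exposure plus covariates and take absolute
#' residuals `d_i`; (ii) regress `d_i` on the same columns by OLS and apply
#' a partial F-test to the exposure columns, keeping covariates in both
#' stages. For a purely categorical exposure without covariates the LAD fit
#' reduces to group medians and the statistic equals the classic
#' Brown-Forsythe F exactly. For continuous exposures this has the same
#' structure as the Glejser / Breusch-Pagan heteroskedasticity tests.
#'
#' @inheritParams location_test
#' @return One-row tibble with `method`, `statistic`, `df1` (number of
#'   exposure columns), `df2` (`n` minus total fitted columns minus 1),
#'   `p_value` and `n_used`.
#' @examples
#' d <- data.frame(x = rnorm(200))
#' d$y <- rnorm(200, sd = exp(d$x / 2))
#' brown_forsythe_ext(d, "y", "x")
#' @export
brown_forsythe_ext <- function(data, outcome, exposure, covariates = NULL) {
  md <- extract_model_data(data, outcome, exposure, covariates)
  res <- bf_extended_fit(md$y, md$X, md$C)
  tibble(
    method = "brown_forsythe_ext",
    statistic = res$statistic, df1 = res$df1, df2 = res$df2,
    p_value = res$p_value, n_used = md$n
  )
}

bf_extended_fit <- function(y, X, C = NULL) {
  X <- build_design(X, name = "exposure")
  full <- if (is.null(C)) X else check_design(cbind(X, C))
  q <- ncol(X)
  n <- length(y)
  stage1 <- fit_lad(y, full)
  d <- stage1$abs_residuals
  # partial F on the exposure columns, covariates kept in both models
  Xi_full <- cbind(1, full)
  rss1 <- sum(qr.resid(qr(Xi_full), d)^2)
  Xi_null <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C)
  rss0 <- sum(qr.resid(qr(Xi_null), d)^2)
  df2 <- n - ncol(full) - 1
  if (rss1 <= 0) {
    abort("zero stage-2 residual variation; statistic undefined",
      class = "jointvar_degenerate_error"
    )
  }
  stat <- ((rss0 - rss1) / q) / (rss1 / df2)
  list(
    statistic = stat, df1 = q, df2 = df2,
    p_value = p_floor(pf(stat, q, df2, lower.tail = FALSE)),
    stage1 = stage1
  )
}

grouped_data <- function(data, outcome, group) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(outcome, group), names(data))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("column(s) not found in data: %s", paste(missing_cols, collapse = ", ")),
      class = "jointvar_data_error"
    )
  }
  keep <- stats::complete.cases(data[c(outcome, group)])
  y <- as.numeric(data[[outcome]][keep])
  g <- factor(data[[group]][keep])
  list(y = y, g = g)
}

check_groups <- function(y, g) {
  g <- as.factor(g)
  if (nlevels(g) < 2) {
    abort("need at least 2 groups", class = "jointvar_data_error")
  }
  sizes <- tabulate(g)
  if (any(sizes < 2)) {
    small <- levels(g)[sizes < 2]
    abort(
      sprintf(
        "every group needs at least 2 observations; too small: %s",
        paste(small, collapse = ", ")
      ),
      class = "jointvar_group_size_error"
    )
  }
  invisible(TRUE)
}
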