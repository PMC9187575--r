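#' Least absolute deviation (median) regression
#'
#' Minimizes the sum of absolute residuals `sum(|y - alpha - X beta|)`. For
#' a design that is the indicator expansion of a single categorical
#' exposure, the optimum is computed exactly as per-group medians (fitted
#' value in each group is the group median, average-of-middle-two for even
#' sizes). For general designs an iteratively reweighted least squares
#' scheme with epsilon-smoothing of the absolute value is used; the fitted
#' values are conditional medians.
#'
#' @inheritParams fit_ols
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @param eps Smoothing floor for the absolute residual weights.
#' @return An object of class `lad_fit`: list with `intercept`, `slopes`,
#'   `fitted`, `abs_residuals`, `objective` (sum of absolute residuals),
#'   `iterations`, `converged`, `exact` (TRUE when the group-median path was
#'   used).
#' @examples
#' g <- rep(c(0, 1), each = 3)
#' fit_lad(c(1, 2, 9, 4, 5, 6), g)$fitted
#' @export
fit_lad <- function(y, X, tol = 1e-8, max_iter = 200, eps = 1e-8) {
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

  if (is_one_factor_design(X)) {
    g <- one_factor_groups(X)
    med <- tapply(y, g, stats::median)
    fitted <- as.numeric(med[as.character(g)])
    ref_med <- unname(med[["0"]])
    slopes <- vapply(seq_len(p), function(j) {
      unname(med[as.character(j)]) - ref_med
    }, numeric(1))
    names(slopes) <- colnames(X)
    res <- y - fitted
    return(structure(
      list(
        intercept = ref_med, slopes = slopes, fitted = fitted,
        abs_residuals = abs(res), objective = sum(abs(res)),
        iterations = 0L, converged = TRUE, exact = TRUE
      ),
      class = "lad_fit"
    ))
  }

  Xi <- cbind(`(Intercept)` = 1, X)
  beta <- qr.coef(qr(Xi), y) # OLS start
  obj <- sum(abs(y - drop(Xi %*% beta)))
  scale_y <- stats::mad(y) + eps
  it <- 0L
  stall <- 0L
  coef_converged <- FALSE
  delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    r <- y - drop(Xi %*% beta)
    w <- 1 / pmax(abs(r), eps * scale_y)
    beta_new <- stats::lm.wfit(Xi, y, w)$coefficients
    delta <- max(abs(beta_new - beta))
    obj_new <- sum(abs(y - drop(Xi %*% beta_new)))
    beta <- beta_new
    if (delta < tol) {
      coef_converged <- TRUE
      break
    }
    # near the optimum IRLS crawls along a face of the L1 surface; once
    # the per-iteration objective gain is negligible, hand over to the
    # exact vertex polish below
    stall <- if (obj - obj_new <= 1e-9 * (1 + abs(obj))) stall + 1L else 0L
    obj <- min(obj, obj_new)
    if (stall >= 5L) break
  }
  # an LAD optimum interpolates at least p + 1 observations: fit exactly
  # through the smallest-residual points and accept strict improvements
  pol <- polish_lad_vertex(Xi, y, beta, sum(abs(y - drop(Xi %*% beta))))
  beta <- pol$beta
  converged <- coef_converged || pol$fixed_point
  if (!converged) {
    abort(
      sprintf(
        "LAD solver did not converge in %d iterations (last step %.3g, objective %.6g)",
        it, delta, pol$obj
      ),
      class = "jointvar_convergence_error"
    )
  }
  fitted <- drop(Xi %*% beta)
  res <- y - fitted
  structure(
    list(
      intercept = unname(beta[1]), slopes = beta[-1], fitted = fitted,
      abs_residuals = abs(res), objective = sum(abs(res)),
      iterations = it, converged = converged, exact = FALSE
    ),
    class = "lad_fit"
  )
}

# Descend over interpolation vertices: an L1 regression optimum passes
# through >= p + 1 data points, so candidate solutions are exact fits
# through subsets of the current smallest-|residual| observations. Only
# strict objective improvements are accepted, so the loop terminates.
polish_lad_vertex <- function(Xi, y, beta, obj, max_rounds = 100L) {
  p1 <- ncol(Xi)
  n <- length(y)
  if (n <= p1) {
    return(list(beta = beta, obj = obj, fixed_point = TRUE))
  }
  for (round in seq_len(max_rounds)) {
    r <- y - drop(Xi %*% beta)
    pool <- order(abs(r))[seq_len(min(p1 + 2L, n))]
    cand <- utils::combn(pool, p1)
    improved <- FALSE
    for (j in seq_len(ncol(cand))) {
      idx <- cand[, j]
      A <- Xi[idx, , drop = FALSE]
      qa <- qr(A)
      if (qa$rank < p1) next
      b_try <- qr.coef(qa, y[idx])
      if (anyNA(b_try)) next
      obj_try <- sum(abs(y - drop(Xi %*% b_try)))
      if (obj_try < obj - 1e-12 * (1 + obj)) {
        beta <- b_try
        obj <- obj_try
        improved <- TRUE
        break
      }
    }
    if (!improved) {
      return(list(beta = beta, obj = obj, fixed_point = TRUE))
    }
  }
  list(beta = beta, obj = obj, fixed_point = FALSE)
}

#' @export
print.lad_fit <- function(x, ...) {
  cat("LAD fit: objective ", format(x$objective),
    if (x$exact) " (exact group medians)" else
      sprintf(" (%d IRLS iterations)", x$iterations),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_lad
#' @param x A `lad_fit` object.
#' @param ... Unused.
#' @export
tidy.lad_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$slopes)),
    estimate = unname(c(x$intercept, x$slopes))
  )
}

#' @rdname fit_lad
#' @export
glance.lad_fit <- function(x, ...) {
  tibble(
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged,
    exact = x$exact,
    nobs = length(x$abs_residuals)
  )
}
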