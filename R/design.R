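#' Build a design matrix from exposure and covariate columns
#'
#' Converts a data frame (or vector/matrix) of predictors into a numeric
#' design matrix suitable for the package's tests. Factors and character
#' columns are expanded to `k - 1` treatment indicators with the first
#' sorted level as reference; numeric columns are passed through. The
#' intercept is never part of the returned matrix: every fitting routine in
#' the package adds its own intercept, and columns that are constant (an
#' implicit user-supplied intercept) are rejected.
#'
#' @param x A vector, factor, matrix or data frame of predictor columns.
#' @param name Label used for unnamed vector input.
#' @return A numeric matrix with one column per (expanded) predictor and a
#'   `"design"` class attribute. Full column rank is checked; collinear
#'   columns raise an error naming the offending columns.
#' @examples
#' build_design(data.frame(dose = c(1, 2, 3, 4), arm = c("a", "a", "b", "b")))
#' @export
build_design <- function(x, name = deparse(substitute(x))) {
  if (inherits(x, "design")) {
    return(x)
  }
  if (is.matrix(x)) {
    cols <- lapply(seq_len(ncol(x)), function(j) x[, j])
    names(cols) <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  } else if (is.data.frame(x)) {
    cols <- as.list(x)
  } else {
    cols <- stats::setNames(list(x), name)
  }
  expanded <- list()
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (is.character(v) || is.logical(v)) v <- factor(v)
    if (is.factor(v)) {
      lev <- sort(unique(as.character(v[!is.na(v)])))
      if (length(lev) < 2) {
        abort(
          sprintf("column '%s' has fewer than 2 levels", nm),
          class = "jointvar_design_error"
        )
      }
      for (l in lev[-1]) {
        expanded[[paste0(nm, l)]] <- as.numeric(as.character(v) == l)
      }
    } else {
      expanded[[nm]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, expanded)
  colnames(X) <- names(expanded)
  check_design(X)
}

check_design <- function(X) {
  if (anyNA(X) || any(!is.finite(X))) {
    abort("design matrix contains non-finite entries",
      class = "jointvar_design_error"
    )
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    abort(sprintf("need more observations (%d) than design columns (%d)", n, p),
      class = "jointvar_design_error"
    )
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    abort(
      sprintf(
        "constant design column(s): %s (the intercept is always included implicitly)",
        paste(colnames(X)[sds == 0], collapse = ", ")
      ),
      class = "jointvar_design_error"
    )
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(Xi))]]
    abort(
      sprintf(
        "design matrix is rank deficient; collinear column(s): %s",
        paste(dropped, collapse = ", ")
      ),
      class = "jointvar_design_error"
    )
  }
  structure(X, class = c("design", class(X)))
}

# Pull outcome / exposure / covariate columns out of a data frame by name.
# Returns list(y, X, C) with C possibly NULL; rows with missing values in
# any used column are dropped (complete-case), and the retained n recorded.
extract_model_data <- function(data, outcome, exposure, covariates = NULL) {
  stopifnot(is.data.frame(data))
  cols <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("column(s) not found in data: %s", paste(missing_cols, collapse = ", ")),
      class = "jointvar_data_error"
    )
  }
  d <- data[cols]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  y <- as.numeric(d[[outcome]])
  if (any(!is.finite(y))) {
    abort("outcome contains non-finite values", class = "jointvar_data_error")
  }
  X <- build_design(d[exposure])
  C <- if (length(covariates) > 0) build_design(d[covariates]) else NULL
  list(y = y, X = X, C = C, n = sum(keep), n_dropped = sum(!keep))
}

# Is X the indicator expansion of a single factor? (All entries 0/1 and at
# most one indicator active per row.) Such designs admit an exact LAD
# solution through group medians.
is_one_factor_design <- function(X) {
  all(X %in% c(0, 1)) && all(rowSums(X) <= 1) && ncol(X) >= 1
}

# Group id per row for a one-factor indicator design (0 = reference level).
one_factor_groups <- function(X) {
  g <- rep(0L, nrow(X))
  for (j in seq_len(ncol(X))) g[X[, j] == 1] <- j
  g
}
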