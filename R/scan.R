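#' Read a feature-by-sample matrix from delimited text
#'
#' Expects tab-delimited text (gzip transparent): first column feature
#' identifiers, header row of sample identifiers, numeric cells (`NA`
#' allowed and tracked as missing). Duplicate identifiers, ragged rows and
#' non-numeric cells raise structured errors with line numbers.
#'
#' @param path File path.
#' @param beta_mode If `TRUE`, all finite values must lie in \[0, 1\]
#'   (methylation beta values); violations name the feature and sample.
#' @return A numeric matrix (features x samples) with row and column
#'   names, class `meth_matrix`, and attribute `beta_mode`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_matrix(matrix(runif(6), 2, 3,
#'   dimnames = list(c("f1", "f2"), c("s1", "s2", "s3"))
#' ), tf)
#' read_matrix(tf, beta_mode = TRUE)
#' @export
read_matrix <- function(path, beta_mode = FALSE) {
  header <- names(readr::read_tsv(path,
    n_max = 0, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  if (length(header) < 2) {
    abort("matrix file needs a feature-ID column plus at least one sample",
      class = "jointvar_io_error"
    )
  }
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    abort(
      sprintf(
        "duplicate sample identifier(s): %s",
        paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
      ),
      class = "jointvar_io_error"
    )
  }
  spec <- stats::setNames(
    c(list(readr::col_character()), rep(list(readr::col_double()), length(sample_ids))),
    header
  )
  # parsing issues surface as a structured error below, not a readr warning
  df <- suppressWarnings(readr::read_tsv(path,
    col_types = do.call(readr::cols, spec), progress = FALSE
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    msg <- paste(
      utils::head(
        sprintf(
          "line %d, column %d: expected %s, got '%s'",
          probs$row, probs$col, probs$expected, probs$actual
        ), 5
      ),
      collapse = "; "
    )
    abort(paste0("malformed matrix file: ", msg), class = "jointvar_io_error")
  }
  feature_ids <- df[[1]]
  if (anyDuplicated(feature_ids)) {
    abort(
      sprintf(
        "duplicate feature identifier(s): %s",
        paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")
      ),
      class = "jointvar_io_error"
    )
  }
  values <- as.matrix(df[-1])
  rownames(values) <- feature_ids
  if (beta_mode) {
    bad <- which(is.finite(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(
        sprintf(
          "value outside [0, 1] under beta mode: feature '%s', sample '%s' (%g)",
          feature_ids[bad[1, 1]], sample_ids[bad[1, 2]],
          values[bad[1, 1], bad[1, 2]]
        ),
        class = "jointvar_io_error"
      )
    }
  }
  structure(values, class = c("meth_matrix", class(values)), beta_mode = beta_mode)
}

#' Write a feature-by-sample matrix as tab-delimited text
#'
#' @param values Numeric matrix with feature row names and sample column
#'   names.
#' @param path Output path (".gz" suffix writes gzip).
#' @param id_col Name of the feature-ID column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(values, path, id_col = "feature_id") {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  df <- tibble::as_tibble(values, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(!!id_col := rownames(values)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a per-sample phenotype/covariate table
#'
#' Tab-delimited text with a header; `id_col` (default the first column)
#' holds unique sample identifiers used to join against matrix columns —
#' alignment is always by identifier, never by position.
#'
#' @param path File path.
#' @param id_col Sample-identifier column name (default: first column).
#' @return A tibble.
#' @export
read_phenotypes <- function(path, id_col = NULL) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(), progress = FALSE,
    show_col_types = FALSE
  )
  id_col <- id_col %||% names(df)[1]
  if (!id_col %in% names(df)) {
    abort(sprintf("id column '%s' not found", id_col),
      class = "jointvar_io_error"
    )
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    abort("duplicate sample identifiers in phenotype table",
      class = "jointvar_io_error"
    )
  }
  attr(df, "id_col") <- id_col
  df
}

#' Scan every feature of a matrix for mean, variance and joint effects
#'
#' Applies the configured battery of tests to each feature (row) of a
#' feature-by-sample matrix against an exposure, adjusting for covariates.
#' Covariates enter regression-style tests (location, extended
#' Brown-Forsythe, JLSp) as additional model columns in both stages;
#' [jlssc()] residualizes both outcome and exposure on them. Samples are
#' matched between matrix and phenotype table by identifier. Features are
#' analysed on their complete cases; features where a test degenerates are
#' flagged, not dropped.
#'
#' @param values A `meth_matrix` from [read_matrix()] or a numeric matrix
#'   with feature row names and sample column names.
#' @param phenotypes Data frame of per-sample phenotype columns; sample
#'   identifiers in `id_col`.
#' @param exposure Name of the exposure column in `phenotypes`.
#' @param covariates Optional character vector of covariate column names.
#' @param tests Subset of `c("ols", "bf_ext", "jlssc", "jlsp")`.
#' @param threshold Hit-declaration p-value threshold (default the
#'   genome-wide 1e-7).
#' @param outlier_sd Optional: per feature, remove outcome outliers beyond
#'   this many SDs before testing.
#' @param id_col Sample-identifier column in `phenotypes` (default: its
#'   first column, or the `id_col` attribute set by [read_phenotypes()]).
#' @param cov_type Covariance flavour for the location test.
#' @return A tibble with one row per feature: `feature_id`, `n_used`,
#'   location results (`beta_mean`, `se_mean`, `p_location`), scale results
#'   (`F_scale`, `p_scale`), joint results (`S_joint`, `df_joint`,
#'   `p_joint`, `p_jlsp`), `n_outliers_removed` and `flag` (empty when
#'   clean, otherwise the degeneracy message). A hit summary with
#'   per-test and Venn-style overlap counts is attached as attribute
#'   `"summary"` (also via [scan_summary()]).
#' @examples
#' pr <- gen_cpg_profiles(3, seed = 1)
#' x <- rbinom(60, 1, 0.5)
#' vals <- t(sapply(seq_len(3), function(i) gen_outcome(pr[i, ], 60, x)))
#' dimnames(vals) <- list(pr$feature, paste0("s", 1:60))
#' ph <- data.frame(sample_id = paste0("s", 1:60), smoke = x)
#' ewas_scan(vals, ph, "smoke", tests = c("ols", "bf_ext"))
#' @export
ewas_scan <- function(values, phenotypes, exposure, covariates = NULL,
                      tests = c("ols", "bf_ext", "jlssc", "jlsp"),
                      threshold = 1e-7, outlier_sd = NULL, id_col = NULL,
                      cov_type = c("classical", "sandwich")) {
  cov_type <- match.arg(cov_type)
  tests <- match.arg(tests, c("ols", "bf_ext", "jlssc", "jlsp"),
    several.ok = TRUE
  )
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("matrix needs feature row names and sample column names",
      class = "jointvar_data_error"
    )
  }
  phenotypes <- as.data.frame(phenotypes)
  id_col <- id_col %||% attr(phenotypes, "id_col") %||% names(phenotypes)[1]
  ids <- as.character(phenotypes[[id_col]])
  common <- intersect(colnames(values), ids)
  if (length(common) == 0) {
    abort("no samples shared between matrix and phenotype table",
      class = "jointvar_data_error"
    )
  }
  values <- values[, common, drop = FALSE]
  phenotypes <- phenotypes[match(common, ids), , drop = FALSE]

  rows <- purrr::map(seq_len(nrow(values)), function(i) {
    scan_one_feature(
      rownames(values)[i], values[i, ], phenotypes, exposure,
      covariates, tests, outlier_sd, cov_type
    )
  })
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$p_location)) && all(is.na(out$p_scale)) &&
    all(is.na(out$p_joint)) && all(is.na(out$p_jlsp))) {
    abort("every feature degenerated; nothing was testable",
      class = "jointvar_degenerate_error"
    )
  }
  attr(out, "summary") <- scan_hit_summary(out, threshold)
  attr(out, "threshold") <- threshold
  structure(out, class = c("ewas_scan", class(out)))
}

scan_one_feature <- function(fid, y, phenotypes, exposure, covariates,
                             tests, outlier_sd, cov_type) {
  d <- phenotypes
  d$.y <- as.numeric(y)
  keep <- stats::complete.cases(d[c(".y", exposure, covariates)])
  d <- d[keep, , drop = FALSE]
  flag <- character(0)
  n_out <- 0L
  if (!is.null(outlier_sd) && sum(keep) >= 3 && stats::sd(d$.y) > 0) {
    mask <- remove_outliers(d$.y, threshold_sd = outlier_sd)
    n_out <- mask$n_removed
    d <- d[mask$keep, , drop = FALSE]
  }
  res <- list(
    feature_id = fid, n_used = nrow(d),
    beta_mean = NA_real_, se_mean = NA_real_, p_location = NA_real_,
    F_scale = NA_real_, p_scale = NA_real_,
    S_joint = NA_real_, df_joint = NA_integer_, p_joint = NA_real_,
    p_jlsp = NA_real_, n_outliers_removed = n_out
  )
  run <- function(test_name, expr) {
    tryCatch(expr, error = function(e) {
      flag <<- c(flag, paste0(test_name, ": ", conditionMessage(e)))
      NULL
    })
  }
  if ("ols" %in% tests) {
    lt <- run("ols", location_test(d, ".y", exposure, covariates, cov_type))
    if (!is.null(lt)) {
      res$beta_mean <- lt$estimate
      res$se_mean <- lt$std_error
      res$p_location <- lt$p_value
    }
  }
  if ("bf_ext" %in% tests) {
    st <- run("bf_ext", brown_forsythe_ext(d, ".y", exposure, covariates))
    if (!is.null(st)) {
      res$F_scale <- st$statistic
      res$p_scale <- st$p_value
    }
  }
  if ("jlssc" %in% tests) {
    jt <- run("jlssc", jlssc(d, ".y", exposure, covariates))
    if (!is.null(jt)) {
      res$S_joint <- jt$statistic
      res$df_joint <- jt$df
      res$p_joint <- jt$p_value
    }
  }
  if ("jlsp" %in% tests) {
    ft <- run("jlsp", jlsp(d, ".y", exposure, covariates))
    if (!is.null(ft)) res$p_jlsp <- ft$p_value
  }
  res$flag <- paste(flag, collapse = "; ")
  tibble::as_tibble(res)
}

scan_hit_summary <- function(out, threshold) {
  hit <- function(p) !is.na(p) & p < threshold
  loc <- hit(out$p_location)
  sca <- hit(out$p_scale)
  joi <- hit(out$p_joint)
  fis <- hit(out$p_jlsp)
  any_hit <- loc | sca | joi | fis
  tibble(
    threshold = threshold,
    n_features = nrow(out),
    n_location = sum(loc),
    n_scale = sum(sca),
    n_jlssc = sum(joi),
    n_jlsp = sum(fis),
    n_any = sum(any_hit),
    n_location_only = sum(loc & !sca & !joi),
    n_scale_only = sum(sca & !loc & !joi),
    n_jlssc_only = sum(joi & !loc & !sca),
    n_location_scale = sum(loc & sca),
    n_location_jlssc = sum(loc & joi),
    n_scale_jlssc = sum(sca & joi),
    n_all_three = sum(loc & sca & joi)
  )
}

#' Hit summary of a scan
#'
#' @param scan Result of [ewas_scan()].
#' @return One-row tibble of per-test hit counts and Venn-style overlaps
#'   at the scan's threshold.
#' @export
scan_summary <- function(scan) {
  attr(scan, "summary")
}

#' Multiplicity-adjust the p-value columns of a scan result
#'
#' Adds `q_*` columns (one per `p_*` column) using [stats::p.adjust()].
#' Provided as a convenience; the scan's own hit declaration uses the fixed
#' genome-wide threshold.
#'
#' @param rows Tibble from [ewas_scan()].
#' @param method Adjustment method (default `"bonferroni"`; any
#'   [stats::p.adjust.methods] value, e.g. `"BH"`).
#' @return `rows` with adjusted-p columns appended.
#' @export
adjust_pvalues <- function(rows, method = "bonferroni") {
  for (col in intersect(
    c("p_location", "p_scale", "p_joint", "p_jlsp"),
    names(rows)
  )) {
    rows[[sub("^p_", "q_", col)]] <- stats::p.adjust(rows[[col]], method = method)
  }
  rows
}

#' Write scan results as tab-delimited text
#'
#' Stable column order, full-precision p-values. An empty result writes a
#' header-only file.
#'
#' @param rows Tibble from [ewas_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  readr::write_tsv(as_tibble(rows), path, progress = FALSE)
  invisible(path)
}
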