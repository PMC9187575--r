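make_scan_fixture <- function(n = 200, n_null = 10, n_mean = 2, n_var = 2,
                              seed = 61, mean_effect = 0.8, var_effect = 1.5) {
  profiles <- gen_cpg_profiles(n_null + n_mean + n_var, seed = seed)
  profiles <- dplyr::mutate(profiles,
    role = rep(c("null", "mean", "var"), c(n_null, n_mean, n_var))
  )
  set.seed(seed + 1)
  x <- rbinom(n, 1, 0.5)
  vals <- t(vapply(seq_len(nrow(profiles)), function(i) {
    eff <- switch(profiles$role[i],
      null = effect_spec(error_family = "normal"),
      mean = effect_spec(mean_effect = mean_effect, error_family = "normal"),
      var = effect_spec(var_effect = var_effect, error_family = "normal")
    )
    gen_outcome(profiles[i, ], n, x, eff, seed = seed + 10 + i)
  }, numeric(n)))
  dimnames(vals) <- list(profiles$feature, sprintf("s%03d", seq_len(n)))
  pheno <- data.frame(
    sample_id = colnames(vals), smoke = x,
    age = round(rnorm(n, 40, 5), 1)
  )
  list(values = vals, pheno = pheno, roles = profiles$role)
}

test_that("matrix files round-trip and malformed input is rejected", {
  fx <- make_scan_fixture(n = 30, n_null = 3, n_mean = 0, n_var = 0)
  tf <- tempfile(fileext = ".tsv")
  write_matrix(fx$values, tf)
  back <- read_matrix(tf, beta_mode = TRUE)
  expect_equal(unclass(back)[, ], fx$values[, ], tolerance = 1e-12)
  expect_identical(rownames(back), rownames(fx$values))

  # missing cells are tracked, not fatal
  v2 <- fx$values
  v2[1, 2] <- NA
  tf2 <- tempfile(fileext = ".tsv")
  write_matrix(v2, tf2)
  expect_true(is.na(read_matrix(tf2)[1, 2]))

  # beta-mode range violation names feature and sample
  v3 <- fx$values
  v3[2, 3] <- 1.3
  tf3 <- tempfile(fileext = ".tsv")
  write_matrix(v3, tf3)
  err <- tryCatch(read_matrix(tf3, beta_mode = TRUE), error = identity)
  expect_s3_class(err, "jointvar_io_error")
  expect_match(conditionMessage(err), rownames(v3)[2])
  expect_match(conditionMessage(err), colnames(v3)[3])

  # duplicate feature ids
  v4 <- fx$values
  rownames(v4)[2] <- rownames(v4)[1]
  tf4 <- tempfile(fileext = ".tsv")
  write_matrix(v4, tf4)
  expect_error(read_matrix(tf4), class = "jointvar_io_error")

  # non-numeric cell reported with its line
  tf5 <- tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "f1\t0.5\toops", "f2\t0.1\t0.2"), tf5)
  err5 <- tryCatch(read_matrix(tf5), error = identity)
  expect_s3_class(err5, "jointvar_io_error")
  expect_match(conditionMessage(err5), "line 2")
})

test_that("samples are joined by identifier, never by position", {
  fx <- make_scan_fixture(n = 120, n_null = 4, n_mean = 1, n_var = 1)
  r1 <- ewas_scan(fx$values, fx$pheno, "smoke", covariates = "age")
  set.seed(1)
  shuffled <- fx$pheno[sample.int(nrow(fx$pheno)), ]
  r2 <- ewas_scan(fx$values, shuffled, "smoke", covariates = "age")
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
  # broken overlap errors
  bad <- fx$pheno
  bad$sample_id <- paste0("zz", bad$sample_id)
  expect_error(ewas_scan(fx$values, bad, "smoke"),
    class = "jointvar_data_error"
  )
})

test_that("planted signals are recovered by the matching tests", {
  fx <- make_scan_fixture(
    n = 500, n_null = 12, n_mean = 3, n_var = 3,
    seed = 71, mean_effect = 0.8, var_effect = 1.5
  )
  res <- ewas_scan(fx$values, fx$pheno, "smoke", threshold = 1e-4)
  expect_equal(nrow(res), 18)
  expect_identical(res$feature_id, rownames(fx$values))
  mean_rows <- fx$roles == "mean"
  var_rows <- fx$roles == "var"
  expect_true(all(res$p_location[mean_rows] < 1e-4))
  expect_true(all(res$p_scale[var_rows] < 1e-4))
  expect_true(all(res$p_joint[mean_rows | var_rows] < 1e-4))
  sm <- scan_summary(res)
  expect_gte(sm$n_location + sm$n_scale + sm$n_jlssc + sm$n_jlsp, sm$n_any)
  expect_equal(sm$n_features, 18)
})

test_that("degenerate features are flagged rows, not omissions", {
  fx <- make_scan_fixture(n = 80, n_null = 3, n_mean = 0, n_var = 0)
  vals <- rbind(fx$values, flatline = rep(0.5, ncol(fx$values)))
  res <- ewas_scan(vals, fx$pheno, "smoke")
  expect_equal(nrow(res), 4)
  flat <- res[res$feature_id == "flatline", ]
  expect_true(is.na(flat$p_joint))
  expect_match(flat$flag, "jlssc")
})

test_that("results files round-trip and empty results write a header", {
  fx <- make_scan_fixture(n = 80, n_null = 3, n_mean = 0, n_var = 0)
  res <- ewas_scan(fx$values, fx$pheno, "smoke")
  tf <- tempfile(fileext = ".tsv")
  write_results(res, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(back$p_joint, res$p_joint, tolerance = 1e-12)
  expect_equal(names(back), names(res))

  tf2 <- tempfile(fileext = ".tsv")
  write_results(res[0, ], tf2)
  expect_equal(nrow(readr::read_tsv(tf2, show_col_types = FALSE)), 0)

  adj <- adjust_pvalues(res, method = "BH")
  expect_true(all(c("q_location", "q_scale", "q_joint", "q_jlsp") %in% names(adj)))
  expect_true(all(adj$q_location >= res$p_location - 1e-15, na.rm = TRUE))
})

test_that("the command-line scanner runs end to end", {
  cli <- system.file("cli", "jointvar.R", package = "jointvar")
  expect_true(nzchar(cli))
  fx <- make_scan_fixture(n = 100, n_null = 4, n_mean = 1, n_var = 0, seed = 91)
  mtx <- tempfile(fileext = ".tsv")
  phe <- tempfile(fileext = ".tsv")
  out <- tempfile(fileext = ".tsv")
  write_matrix(fx$values, mtx)
  readr::write_tsv(fx$pheno, phe)
  status <- system2(
    file.path(R.home("bin"), "Rscript"),
    c(
      cli, "scan", "--matrix", mtx, "--pheno", phe, "--exposure", "smoke",
      "--covariates", "age", "--threshold", "1e-4", "--beta-mode",
      "--out", out
    ),
    stdout = FALSE, stderr = FALSE
  )
  expect_equal(status, 0)
  res <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(res), 5)
  sidecar <- jsonlite::read_json(paste0(out, ".json"))
  expect_equal(sidecar$package, "jointvar")
  expect_equal(sidecar$exposure, "smoke")
})
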