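test_that("the score statistic matches a dense Kronecker oracle", {
  # small fixed fixture, binary exposure
  y <- c(0.41, 0.52, 0.47, 0.63, 0.38, 0.55, 0.49, 0.71)
  x <- c(0, 1, 0, 1, 0, 1, 0, 1)
  d <- data.frame(y = y, x = x)
  mine <- jlssc(d, "y", "x")
  expect_equal(mine$statistic, jlssc_dense_oracle(y, cbind(x)),
    tolerance = 1e-10
  )
  # and on random multi-column designs
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("x1", "x2")))
    yy <- rnorm(60)
    dd <- data.frame(y = yy, x1 = X[, 1], x2 = X[, 2])
    expect_equal(
      jlssc(dd, "y", c("x1", "x2"))$statistic,
      jlssc_dense_oracle(yy, X),
      tolerance = 1e-10
    )
  }
})

test_that("S is invariant to affine y transforms and linear X transforms", {
  set.seed(21)
  d <- data.frame(y = rnorm(80), x1 = rnorm(80), x2 = rnorm(80))
  s0 <- jlssc(d, "y", c("x1", "x2"))$statistic
  d2 <- d
  d2$y <- 2.5 * d$y - 7
  expect_equal(jlssc(d2, "y", c("x1", "x2"))$statistic, s0, tolerance = 1e-8)
  for (seed in 1:5) {
    set.seed(100 + seed)
    A <- matrix(rnorm(4), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
    XA <- as.matrix(d[c("x1", "x2")]) %*% A
    d3 <- data.frame(y = d$y, x1 = XA[, 1], x2 = XA[, 2])
    expect_equal(jlssc(d3, "y", c("x1", "x2"))$statistic, s0,
      tolerance = 1e-8 * max(1, s0)
    )
  }
})

test_that("degrees of freedom track the exposure columns", {
  set.seed(5)
  d <- data.frame(
    y = rnorm(200), x = rnorm(200),
    g = factor(sample(0:2, 200, TRUE))
  )
  expect_equal(jlssc(d, "y", "x")$df, 2)
  expect_equal(jlssc(d, "y", "x", include_square = TRUE)$df, 4)
  expect_equal(jlssc(d, "y", "g")$df, 4) # 2 * (k - 1)
  st <- attr(jlssc(d, "y", "x"), "state")
  expect_true(st$assumes_constant_skew_kurtosis)
  expect_equal(st$Sigma_hat[1, 1], st$sigma2_hat, tolerance = 1e-12)
  expect_lt(abs(mean(st$y_centered)), 1e-10)
  expect_lt(abs(mean(st$d_centered)), 1e-10)
})

test_that("degenerate inputs raise named errors", {
  d <- data.frame(y = rep(1, 50), x = rnorm(50))
  expect_error(jlssc(d, "y", "x"), class = "jointvar_degenerate_error")
  d2 <- data.frame(y = rnorm(10), x = rnorm(10))
  expect_error(
    jlssc(d2[1:8, ], "y", "x", include_square = TRUE),
    class = "jointvar_data_error"
  )
})

test_that("covariate adjustment residualizes both sides", {
  set.seed(31)
  n <- 400
  c1 <- rnorm(n)
  x <- 0.8 * c1 + rnorm(n)
  y <- 1.5 * c1 + rnorm(n) # y depends on the covariate only
  d <- data.frame(y = y, x = x, c1 = c1)
  p_adj <- jlssc(d, "y", "x", covariates = "c1")$p_value
  p_raw <- jlssc(d, "y", "x")$p_value
  expect_lt(p_raw, 0.05) # confounded without adjustment
  expect_gt(p_adj, 0.001) # adjustment removes the induced signal
})

test_that("jlsp equals the Fisher combination of its stored components", {
  fc <- fisher_combine(c(0.05, 0.05))
  expect_equal(fc$statistic, -2 * 2 * log(0.05), tolerance = 1e-10)
  expect_equal(fc$p_value, pchisq(fc$statistic, 4, lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_equal(fisher_combine(c(1, 1))$statistic, 0)
  expect_equal(fisher_combine(c(1, 1))$p_value, 1)
  expect_error(fisher_combine(c(0, 0.5)), class = "jointvar_data_error")

  set.seed(3)
  d <- data.frame(y = rnorm(120), x = rnorm(120))
  r <- jlsp(d, "y", "x")
  expect_equal(r$statistic, -2 * (log(r$p_location) + log(r$p_scale)),
    tolerance = 1e-12
  )
  expect_equal(r$p_value, pchisq(r$statistic, 4, lower.tail = FALSE),
    tolerance = 1e-12
  )
})

test_that("robust variant agrees with the plain test under normality at large n", {
  set.seed(12)
  d <- data.frame(y = rnorm(10000), x = rnorm(10000))
  s_plain <- jlssc(d, "y", "x")$statistic
  s_rob <- jlssc(d, "y", "x", robust = TRUE)$statistic
  expect_lt(abs(s_rob - s_plain) / max(s_plain, 1), 0.10)
})

test_that("robust variant is better calibrated under exposure-dependent kurtosis", {
  n_reps <- 1000
  p_plain <- p_rob <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(60000 + i)
    x <- rbinom(400, 1, 0.5)
    # same mean and variance in both groups, kurtosis differs with x
    y <- ifelse(x == 1, rt(400, df = 4) / sqrt(2), rnorm(400))
    d <- data.frame(y = y, x = x)
    p_plain[i] <- jlssc(d, "y", "x")$p_value
    p_rob[i] <- jlssc(d, "y", "x", robust = TRUE)$p_value
  }
  r_plain <- mean(p_plain <= 0.05)
  r_rob <- mean(p_rob <= 0.05)
  se <- sqrt(0.05 * 0.95 / n_reps)
  expect_lt(abs(r_rob - 0.05), abs(r_plain - 0.05) + 2 * se)
})

test_that("robust variant does not beat the plain test's power under normality", {
  pw <- power_experiment(c("jlssc", "jlssc_robust"), "binary",
    effect_spec(mean_effect = 0.35, var_effect = 0.4, error_family = "normal"),
    n = 1000, n_reps = 300, threshold = 1e-7, seed = 414
  )
  r <- setNames(pw$rate, pw$test)
  se <- sqrt(max(r) * (1 - max(r)) / 300)
  expect_lte(r[["jlssc_robust"]], r[["jlssc"]] + 2 * se)
  expect_gt(r[["jlssc"]], 0) # the setting is informative
})

test_that("outlier trimming is exposed and reported", {
  set.seed(77)
  d <- data.frame(y = c(rnorm(200), 25), x = c(rbinom(200, 1, 0.5), 1))
  r <- jlssc(d, "y", "x", outlier_sd = 3)
  expect_equal(r$n_outliers_removed, 1)
  expect_equal(r$n_used, 200)
})
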