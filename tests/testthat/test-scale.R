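test_that("Bartlett statistic matches the textbook formula", {
  # equal variances: statistic 0, p 1
  d0 <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  r0 <- bartlett_test(d0, "y", "g")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  y <- c(1, 2, 3, 4, 10, 20, 30, 40)
  g <- rep(c("a", "b"), each = 4)
  r <- bartlett_test(data.frame(y = y, g = g), "y", "g")
  # direct evaluation: T = ((n-k) ln s2p - sum (nj-1) ln s2j) / C
  s2 <- tapply(y, g, var)
  nj <- c(4, 4)
  n <- 8
  k <- 2
  s2p <- sum((nj - 1) * s2) / (n - k)
  C <- 1 + (sum(1 / (nj - 1)) - 1 / (n - k)) / (3 * (k - 1))
  T_oracle <- ((n - k) * log(s2p) - sum((nj - 1) * log(s2))) / C
  expect_equal(r$statistic, T_oracle, tolerance = 1e-10)
  expect_equal(r$df1, 1)
  expect_error(
    bartlett_test(
      data.frame(y = c(1, 1, 1, 2, 3, 4), g = rep(c("a", "b"), each = 3)),
      "y", "g"
    ),
    class = "jointvar_degenerate_error"
  )
})

test_that("classic Brown-Forsythe matches hand evaluation and car oracle", {
  # identical spread in both groups
  d0 <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  r0 <- brown_forsythe(d0, "y", "g")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  # fixed fixture: z-values {2,1,0,1,2} and {0,0,0,0,0}
  y <- c(0, 1, 2, 3, 4, rep(2, 5))
  g <- rep(c("a", "b"), each = 5)
  r <- brown_forsythe(data.frame(y = y, g = g), "y", "g")
  expect_equal(r$statistic, bf_by_anova(y, g), tolerance = 1e-10)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 8)

  for (seed in 1:5) {
    d <- make_grouped_df(k = 3, n = 60, seed = seed)
    mine <- brown_forsythe(d, "y", "g")$statistic
    oracle <- car::leveneTest(y ~ g, data = d, center = median)[1, "F value"]
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("degenerate groupings are reported as errors, not dropped", {
  d <- data.frame(y = rep(1, 10), g = rep(c("a", "b"), 5))
  expect_error(brown_forsythe(d, "y", "g"), class = "jointvar_degenerate_error")
  d2 <- data.frame(y = rnorm(5), g = c("a", "a", "a", "a", "b"))
  expect_error(brown_forsythe(d2, "y", "g"), class = "jointvar_group_size_error")
})

test_that("extended BF equals classic BF on categorical designs", {
  for (seed in 1:8) {
    k <- sample(c(2, 3, 5), 1)
    d <- make_grouped_df(k = k, n = 40 + 10 * k, seed = 100 + seed)
    classic <- brown_forsythe(d, "y", "g")
    extended <- brown_forsythe_ext(d, "y", "g")
    expect_equal(extended$statistic, classic$statistic, tolerance = 1e-10)
    expect_equal(extended$df1, classic$df1)
    expect_equal(extended$df2, classic$df2)
  }
})

test_that("BF is invariant to affine transforms of the outcome", {
  d <- make_grouped_df(k = 3, n = 75, seed = 55, sds = c(1, 1.5, 2))
  base <- brown_forsythe(d, "y", "g")$statistic
  d$y <- -3.2 * d$y + 11
  expect_equal(brown_forsythe(d, "y", "g")$statistic, base, tolerance = 1e-10)
})

test_that("the BF statistic grows with the between-group variance ratio", {
  med_stat <- function(ratio) {
    stats <- vapply(1:40, function(seed) {
      d <- make_grouped_df(k = 2, n = 100, seed = 7000 + seed, sds = c(1, ratio))
      brown_forsythe(d, "y", "g")$statistic
    }, numeric(1))
    median(stats)
  }
  expect_gt(med_stat(2), med_stat(1))
  expect_gt(med_stat(4), med_stat(2))
})

test_that("extended BF detects a continuous-exposure scale effect", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(1000)
    d <- data.frame(x = x, y = rnorm(1000, sd = exp(x / 2)))
    if (brown_forsythe_ext(d, "y", "x")$p_value < 1e-7) hits <- hits + 1
  }
  expect_gte(hits, 6) # strong scale signal recovered in most replicates
})

test_that("covariates are kept in both stages of the extended test", {
  set.seed(99)
  d <- data.frame(
    x = rnorm(300), batch = factor(sample(c("b1", "b2"), 300, TRUE))
  )
  d$y <- 0.5 * as.integer(d$batch) + rnorm(300)
  r <- brown_forsythe_ext(d, "y", "x", covariates = "batch")
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 300 - 2 - 1) # exposure + batch indicator + intercept
  expect_true(r$p_value > 0 && r$p_value <= 1)
})

test_that("null p-values of classic BF are approximately uniform", {
  n_reps <- 2000
  p <- vapply(seq_len(n_reps), function(i) {
    set.seed(40000 + i)
    y <- rnorm(100)
    g <- rep(c("a", "b"), each = 50)
    brown_forsythe(data.frame(y = y, g = g), "y", "g")$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})
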