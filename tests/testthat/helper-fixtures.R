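# Shared fixture builders and independent oracles.

# Random grouped data frame with k groups of size >= 2.
make_grouped_df <- function(k, n, seed, sds = rep(1, k)) {
  set.seed(seed)
  g <- factor(sample(letters[seq_len(k)], n, replace = TRUE))
  while (min(table(g)) < 2) {
    g <- factor(sample(letters[seq_len(k)], n, replace = TRUE))
  }
  y <- rnorm(n, sd = sds[as.integer(g)])
  data.frame(y = y, g = g)
}

# Independent evaluation of the Brown-Forsythe F from its definition:
# one-way ANOVA of absolute deviations from group medians.
bf_by_anova <- function(y, g) {
  g <- factor(g)
  z <- abs(y - ave(y, g, FUN = median))
  summary(aov(z ~ g))[[1]]["g", "F value"]
}

# Brute-force LAD for one predictor: the optimum interpolates two points.
lad_brute_force <- function(y, x) {
  n <- length(y)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      obj <- sum(abs(y - a - b * x))
      if (obj < best) best <- obj
    }
  }
  best
}

# Dense-matrix evaluation of the joint score statistic: build theta-hat and
# the full Kronecker matrix explicitly and multiply.
jlssc_dense_oracle <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  sigma2 <- mean(yc^2)
  dc <- yc^2 - sigma2
  XtX <- crossprod(Xc)
  beta <- solve(XtX, crossprod(Xc, yc))
  delta <- solve(XtX, crossprod(Xc, dc))
  theta <- rbind(beta, delta)
  Sigma <- matrix(c(mean(yc^2), mean(yc * dc), mean(yc * dc), mean(dc^2)), 2)
  M <- kronecker(solve(Sigma), XtX)
  drop(t(theta) %*% M %*% theta)
}

# Monte-Carlo rejection band: nominal +/- 3 binomial SEs.
mc_band <- function(alpha, n_reps, width = 3) {
  se <- sqrt(alpha * (1 - alpha) / n_reps)
  c(alpha - width * se, alpha + width * se)
}
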