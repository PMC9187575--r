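#' Generate methylation-like feature profiles
#'
#' Draws per-feature (mean, SD) pairs emulating the marginal distribution
#' of array methylation beta values: a three-component mixture of
#' low-methylated (mean near 0.1), high-methylated (mean near 0.9) and
#' intermediate (uniform on 0.2-0.8) features with weights 0.35/0.35/0.30,
#' and an SD drawn as a feasible fraction of the binomial-bound
#' `sqrt(m * (1 - m))`. Instantiated as beta distributions, the population
#' is calibrated so that most features are near-symmetric and light-tailed
#' (sample skewness in (-1, 1), excess kurtosis below 3) while a sizeable
#' minority is strongly skewed or heavy-tailed, as observed on real arrays.
#'
#' @param n_features Number of profiles (>= 1).
#' @param seed Integer seed; the same seed reproduces the same profiles.
#' @return A tibble with columns `feature`, `m` (mean) and `s` (SD), of
#'   class `cpg_profiles`.
#' @examples
#' gen_cpg_profiles(5, seed = 1)
#' @export
gen_cpg_profiles <- function(n_features, seed = 1) {
  if (!is.numeric(n_features) || n_features < 1) {
    abort("n_features must be >= 1", class = "jointvar_data_error")
  }
  n_features <- as.integer(n_features)
  set.seed(seed)
  comp <- sample.int(3, n_features, replace = TRUE, prob = c(0.35, 0.35, 0.30))
  m <- numeric(n_features)
  m[comp == 1] <- runif(sum(comp == 1), 0.03, 0.15)
  m[comp == 2] <- runif(sum(comp == 2), 0.85, 0.97)
  m[comp == 3] <- runif(sum(comp == 3), 0.20, 0.80)
  # SD as a fraction of the feasibility bound sqrt(m(1-m)); features near
  # the 0/1 boundaries are the skewed/heavy-tailed minority seen on real
  # arrays
  frac <- ifelse(comp == 3, runif(n_features, 0.05, 0.35),
    runif(n_features, 0.05, 0.30)
  )
  s <- frac * sqrt(m * (1 - m))
  bad <- which(s^2 >= m * (1 - m))
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > 1000) {
      abort("could not draw feasible (mean, sd) profiles",
        class = "jointvar_simulation_error"
      )
    }
    s[bad] <- runif(length(bad), 0.05, 0.6) * sqrt(m[bad] * (1 - m[bad]))
    bad <- bad[s[bad]^2 >= m[bad] * (1 - m[bad])]
  }
  structure(
    tibble(feature = paste0("cpg", seq_len(n_features)), m = m, s = s),
    class = c("cpg_profiles", class(tibble())),
    seed = seed
  )
}

#' Implied beta-distribution skewness of feature profiles
#'
#' The skewness of a beta variable with the profile's (mean, SD); useful
#' for stratifying generated features into near-symmetric and strongly
#' skewed subsets (for example `abs(profile_skewness(p)) >= 1.5` selects
#' the strongly skewed tail used in robustness contrasts).
#'
#' @param profiles Tibble from [gen_cpg_profiles()] (columns `m`, `s`).
#' @return Numeric vector of skewness values.
#' @examples
#' profile_skewness(gen_cpg_profiles(5, seed = 1))
#' @export
profile_skewness <- function(profiles) {
  m <- profiles$m
  s <- profiles$s
  t <- m * (1 - m) / s^2 - 1
  a <- m * t
  b <- (1 - m) * t
  2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
}

beta_shapes <- function(m, s) {
  t <- m * (1 - m) / s^2 - 1
  if (t <= 0) {
    abort("infeasible (mean, sd): sd^2 must be < m * (1 - m)",
      class = "jointvar_simulation_error"
    )
  }
  c(shape1 = m * t, shape2 = (1 - m) * t)
}

#' Specify a simulated exposure
#'
#' The three exposure generators used throughout the simulation study:
#' `binary` is Bernoulli(0.5), `continuous` is standard normal,
#' `categorical3` is Binomial(2, 0.3) yielding three categories 0/1/2.
#'
#' @param kind One of `"binary"`, `"continuous"`, `"categorical3"`.
#' @return An `exposure_spec` list with a `draw(n)` generator.
#' @examples
#' spec <- exposure_spec("binary")
#' table(spec$draw(10))
#' @export
exposure_spec <- function(kind = c("binary", "continuous", "categorical3")) {
  kind <- match.arg(kind)
  draw <- switch(kind,
    binary = function(n) {
      x <- rbinom(n, 1, 0.5)
      tries <- 0
      while (min(tabulate(factor(x, levels = 0:1))) < 2 && tries < 100) {
        x <- rbinom(n, 1, 0.5)
        tries <- tries + 1
      }
      x
    },
    continuous = function(n) rnorm(n),
    categorical3 = function(n) {
      x <- rbinom(n, 2, 0.3)
      tries <- 0
      while (min(tabulate(factor(x, levels = 0:2))) < 2 && tries < 100) {
        x <- rbinom(n, 2, 0.3)
        tries <- tries + 1
      }
      factor(x, levels = 0:2)
    }
  )
  structure(list(kind = kind, draw = draw), class = "exposure_spec")
}

#' Specify mean/variance effects and the residual-error family
#'
#' @param mean_effect Mean shift per exposure unit, in units of the
#'   feature's SD (0 = none).
#' @param var_effect Multiplicative SD ratio per exposure unit: the
#'   residual SD is scaled by `(1 + var_effect)^z` with `z` the
#'   standardized exposure (0 = none).
#' @param error_family Residual distribution: `"beta"` (method-of-moments
#'   beta deviate, the methylation-like default), `"normal"`,
#'   `"heavy_tailed"` (t with 4 df, rescaled) or `"skewed"` (shifted
#'   log-normal, rescaled).
#' @param inject_outlier Replace one random observation with
#'   `mean + 6 * SD`.
#' @return An `effect_spec` list.
#' @examples
#' effect_spec(mean_effect = 0.5)
#' @export
effect_spec <- function(mean_effect = 0, var_effect = 0,
                        error_family = c("beta", "normal", "heavy_tailed", "skewed"),
                        inject_outlier = FALSE) {
  error_family <- match.arg(error_family)
  stopifnot(var_effect >= 0)
  structure(
    list(
      mean_effect = mean_effect, var_effect = var_effect,
      error_family = error_family, inject_outlier = inject_outlier
    ),
    class = "effect_spec"
  )
}

#' Simulate a methylation-like outcome with mean and variance effects
#'
#' Generates `n` outcome values with baseline mean `m` and SD `s` (one
#' feature profile), then applies the exposure effects of an
#' [effect_spec()]: the mean effect adds `mean_effect * s` per unit of
#' centered exposure; the variance effect scales the centered residual by
#' `(1 + var_effect)^z` with `z` the standardized exposure. Residuals come
#' from the chosen error family, moment-matched to (0, s^2). Values are
#' clipped to (1e-6, 1 - 1e-6) so beta-value transforms stay defined.
#'
#' @param profile One row of [gen_cpg_profiles()] output, or any list with
#'   elements `m` and `s`.
#' @param n Sample size.
#' @param exposure Numeric vector or factor of length `n`.
#' @param effect An [effect_spec()].
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` in (0, 1).
#' @examples
#' pr <- gen_cpg_profiles(1, seed = 2)
#' y <- gen_outcome(pr[1, ], 100, rbinom(100, 1, 0.5), effect_spec(0.5))
#' @export
gen_outcome <- function(profile, n, exposure, effect = effect_spec(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- profile$m
  s <- profile$s
  x <- as.numeric(exposure)
  if (length(x) != n) {
    abort("exposure must have length n", class = "jointvar_data_error")
  }
  e <- switch(effect$error_family,
    beta = {
      sh <- beta_shapes(m, s)
      stats::rbeta(n, sh[1], sh[2]) - m
    },
    normal = rnorm(n, 0, s),
    heavy_tailed = rt(n, df = 4) * s / sqrt(2),
    skewed = (rlnorm(n) - exp(0.5)) / sqrt((exp(1) - 1) * exp(1)) * s
  )
  if (effect$var_effect > 0) {
    z <- (x - mean(x)) / max(stats::sd(x), .Machine$double.eps)
    e <- e * (1 + effect$var_effect)^z
  }
  y <- m + effect$mean_effect * s * (x - mean(x)) + e
  if (effect$inject_outlier) {
    y[sample.int(n, 1)] <- m + 6 * s
  }
  pmin(pmax(y, 1e-6), 1 - 1e-6)
}

#' Registry of feature-level tests
#'
#' Each registry entry is a function `(y, x, covariates) -> p-value` so the
#' simulation engines and the scan can run any battery by name. Available:
#' `ols` (classical location test), `ols_sandwich`, `bartlett`, `bf`
#' (classic Brown-Forsythe; both require a categorical exposure), `bf_ext`
#' (extended Brown-Forsythe), `jlsp`, `jlssc`, `jlssc_sq` (with squared
#' exposure), `jlssc_robust`.
#'
#' @param names Optional character vector selecting a subset (errors on
#'   unknown names).
#' @return Named list of test functions.
#' @examples
#' names(test_registry())
#' @export
test_registry <- function(names = NULL) {
  reg <- list(
    ols = function(y, x, covariates = NULL) {
      location_test_fit(y, build_design(x), covariates, cov_type = "classical")$p_value
    },
    ols_sandwich = function(y, x, covariates = NULL) {
      location_test_fit(y, build_design(x), covariates, cov_type = "sandwich")$p_value
    },
    bartlett = function(y, x, covariates = NULL) {
      bartlett_fit(y, factor(x))$p_value
    },
    bf = function(y, x, covariates = NULL) {
      bf_classic_fit(y, factor(x))$p_value
    },
    bf_ext = function(y, x, covariates = NULL) {
      bf_extended_fit(y, build_design(x), covariates)$p_value
    },
    jlsp = function(y, x, covariates = NULL) {
      jlsp_fit(y, build_design(x), covariates)$p_value
    },
    jlssc = function(y, x, covariates = NULL) {
      jlssc_fit(y, build_design(x), covariates)$p_value
    },
    jlssc_sq = function(y, x, covariates = NULL) {
      jlssc_fit(y, build_design(x), covariates, include_square = TRUE)$p_value
    },
    jlssc_robust = function(y, x, covariates = NULL) {
      jlssc_fit(y, build_design(x), covariates, robust = TRUE)$p_value
    }
  )
  if (is.null(names)) {
    return(reg)
  }
  unknown <- setdiff(names, base::names(reg))
  if (length(unknown) > 0) {
    abort(
      sprintf("unknown test(s): %s", paste(unknown, collapse = ", ")),
      class = "jointvar_data_error"
    )
  }
  reg[names]
}

# The engines are test-agnostic: `tests` may be registry names or a named
# list of callables with the (y, x, covariates) -> p contract.
resolve_tests <- function(tests) {
  if (is.list(tests) && all(vapply(tests, is.function, logical(1)))) {
    if (is.null(names(tests)) || any(names(tests) == "")) {
      abort("a list of test functions must be fully named",
        class = "jointvar_data_error"
      )
    }
    return(tests)
  }
  test_registry(tests)
}

draw_null_outcome <- function(source, n, profiles = NULL) {
  switch(source,
    normal = rnorm(n),
    t4 = rt(n, df = 4),
    lognormal = rlnorm(n),
    contaminated_normal = {
      heavy <- runif(n) < 0.10
      rnorm(n, mean = ifelse(heavy, 5, 0), sd = 1)
    },
    profile_resample = {
      pr <- profiles[sample.int(nrow(profiles), 1), ]
      sh <- beta_shapes(pr$m, pr$s)
      stats::rbeta(n, sh[1], sh[2])
    },
    abort(sprintf("unknown outcome source '%s'", source),
      class = "jointvar_data_error"
    )
  )
}

#' Type-I-error experiment
#'
#' Simulates replicates with the exposure independent of the outcome and
#' reports per-test rejection rates at each significance level, with
#' binomial Monte-Carlo standard errors. Per-replicate seeds are spawned
#' deterministically from the master seed, so results are bit-reproducible
#' for a given (configuration, seed) pair.
#'
#' @param tests Character vector of [test_registry()] names.
#' @param exposure Exposure kind (see [exposure_spec()]) or an
#'   `exposure_spec`.
#' @param outcome_source One of `"normal"`, `"t4"`, `"lognormal"`,
#'   `"contaminated_normal"`, `"profile_resample"` (beta outcomes drawn
#'   from `profiles`).
#' @param n Sample size per replicate.
#' @param n_reps Number of replicates (>= 100).
#' @param alphas Significance levels at which to report rejection rates.
#' @param seed Master seed.
#' @param profiles Profiles tibble for `outcome_source =
#'   "profile_resample"` (default: 1000 fresh profiles).
#' @param keep_pvalues Store the raw p-value matrix (for QQ plots).
#' @return A `sim_result` tibble: one row per test x alpha with `rate` and
#'   `mc_se`; config and optional p-values attached as attributes.
#' @examples
#' type1_experiment("ols", "binary", "normal", n = 100, n_reps = 200, seed = 1)
#' @export
type1_experiment <- function(tests, exposure = "binary",
                             outcome_source = "normal", n = 1000,
                             n_reps = 2000, alphas = 0.05, seed = 1,
                             profiles = NULL, keep_pvalues = FALSE) {
  if (n_reps < 100) {
    abort("n_reps must be >= 100", class = "jointvar_data_error")
  }
  reg <- resolve_tests(tests)
  es <- if (inherits(exposure, "exposure_spec")) exposure else exposure_spec(exposure)
  if (identical(outcome_source, "profile_resample") && is.null(profiles)) {
    profiles <- gen_cpg_profiles(1000, seed = spawn_seed(seed, 0))
  }
  P <- matrix(NA_real_, n_reps, length(reg),
    dimnames = list(NULL, names(reg))
  )
  for (i in seq_len(n_reps)) {
    set_rep_seed(seed, i)
    x <- es$draw(n)
    y <- draw_null_outcome(outcome_source, n, profiles)
    for (tn in names(reg)) {
      P[i, tn] <- reg[[tn]](y, x)
    }
  }
  sim_result_from_p(P,
    alphas = alphas, n = n, seed = seed,
    config = list(
      kind = "type1", tests = names(reg), exposure = es$kind,
      outcome_source = outcome_source, n = n, n_reps = n_reps
    ),
    keep_pvalues = keep_pvalues
  )
}

#' Power experiment at a genome-wide threshold
#'
#' Simulates replicates with the exposure affecting the mean and/or
#' variance of a methylation-like outcome. In each replicate one feature
#' profile is selected at random, the outcome is generated with
#' [gen_outcome()], each test is applied, and power is the proportion of
#' replicates with p below `threshold`.
#'
#' @inheritParams type1_experiment
#' @param effect An [effect_spec()].
#' @param threshold Significance threshold (default the genome-wide 1e-7).
#' @param profiles Profiles to draw from (default: 1000 fresh profiles).
#' @return A `sim_result` tibble, one row per test.
#' @examples
#' power_experiment("ols", "binary", effect_spec(mean_effect = 0.5),
#'   n = 200, n_reps = 100, threshold = 0.01, seed = 1
#' )
#' @export
power_experiment <- function(tests, exposure = "binary",
                             effect = effect_spec(), n = 1000,
                             n_reps = 1000, threshold = 1e-7, seed = 1,
                             profiles = NULL, keep_pvalues = FALSE) {
  reg <- resolve_tests(tests)
  es <- if (inherits(exposure, "exposure_spec")) exposure else exposure_spec(exposure)
  if (is.null(profiles)) {
    profiles <- gen_cpg_profiles(1000, seed = spawn_seed(seed, 0))
  }
  P <- matrix(NA_real_, n_reps, length(reg),
    dimnames = list(NULL, names(reg))
  )
  for (i in seq_len(n_reps)) {
    set_rep_seed(seed, i)
    pr <- profiles[sample.int(nrow(profiles), 1), ]
    x <- es$draw(n)
    y <- gen_outcome(pr, n, x, effect)
    for (tn in names(reg)) {
      P[i, tn] <- reg[[tn]](y, x)
    }
  }
  sim_result_from_p(P,
    alphas = threshold, n = n, seed = seed,
    config = list(
      kind = "power", tests = names(reg), exposure = es$kind,
      effect = unclass(effect), n = n, n_reps = n_reps,
      threshold = threshold
    ),
    keep_pvalues = keep_pvalues
  )
}

sim_result_from_p <- function(P, alphas, n, seed, config,
                              keep_pvalues = FALSE) {
  n_reps <- nrow(P)
  rows <- tidyr::expand_grid(
    test = colnames(P), alpha = alphas
  )
  rows <- dplyr::mutate(rows,
    rate = purrr::map2_dbl(.data$test, .data$alpha, function(tn, a) {
      mean(P[, tn] <= a)
    }),
    mc_se = sqrt(.data$rate * (1 - .data$rate) / n_reps),
    n_reps = n_reps, n = n, seed = seed
  )
  out <- structure(rows, class = c("sim_result", class(rows)))
  attr(out, "config") <- config
  if (keep_pvalues) attr(out, "p_values") <- P
  out
}

#' Genomic inflation factor of a set of p-values
#'
#' `lambda = median(qchisq(p, df = 1, lower = FALSE)) / qchisq(0.5, 1)`.
#' Values near 1 indicate a calibrated test; above 1, inflation.
#'
#' @param p Vector of p-values in (0, 1].
#' @return A single number.
#' @examples
#' qq_lambda(runif(1000))
#' @export
qq_lambda <- function(p) {
  if (length(p) == 0) {
    abort("empty p-value vector", class = "jointvar_data_error")
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]", class = "jointvar_data_error")
  }
  stats::median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
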