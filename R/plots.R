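#' QQ plot of p-values on the -log10 scale
#'
#' Compares observed p-value quantiles with the uniform expectation; the
#' genomic inflation factor [qq_lambda()] is shown in the subtitle.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param label Optional series label (used when overlaying calls with
#'   `ggplot2` layering).
#' @return A `ggplot` object.
#' @examples
#' plot_qq(runif(500))
#' @export
plot_qq <- function(p, label = NULL) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]", class = "jointvar_data_error")
  }
  n <- length(p)
  df <- tibble(
    expected = -log10(stats::ppoints(n)),
    observed = -log10(sort(p))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = label,
      subtitle = sprintf("lambda = %.3f", qq_lambda(p))
    ) +
    ggplot2::theme_minimal()
}

#' Plot rejection rates of a simulation experiment
#'
#' One point per test (and per significance level), with +/- 2 Monte-Carlo
#' standard-error bars; for type-I-error experiments the nominal level is
#' drawn as a dashed line.
#'
#' @param object A `sim_result` from [type1_experiment()] or
#'   [power_experiment()].
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.sim_result <- function(object, ...) {
  cfg <- attr(object, "config")
  gg <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$test, y = .data$rate)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$rate - 2 * .data$mc_se, 0),
      ymax = pmin(.data$rate + 2 * .data$mc_se, 1)
    )) +
    ggplot2::labs(
      x = NULL,
      y = if (identical(cfg$kind, "power")) "power" else "rejection rate",
      subtitle = sprintf(
        "%s exposure, n = %d, %d replicates",
        cfg$exposure, object$n[1], object$n_reps[1]
      )
    ) +
    ggplot2::theme_minimal()
  if (identical(cfg$kind, "type1")) {
    gg <- gg + ggplot2::geom_hline(
      yintercept = unique(object$alpha),
      linetype = 2, colour = "grey40"
    ) + ggplot2::facet_wrap(~alpha, scales = "free_y")
  }
  gg
}
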