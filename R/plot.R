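#' Plot an estimator-property sweep
#'
#' Draws the three standard panels for a Monte Carlo sweep: mean estimate,
#' empirical bias, or standard error, as a function of the pre-post
#' correlation, one line per pre-intervention SD, faceted by SMD family.
#' For the SE panel both the empirical SE and (where a closed form exists)
#' the formula-based SE are drawn, since either may be the quantity of
#' interest.
#'
#' @param object An `smd_sweep` tibble from [sim_sweep()].
#' @param metric `"estimate"`, `"bias"` or `"se"`.
#' @param corrected Plot the Hedges-corrected (`TRUE`) or uncorrected
#'   (default) estimator.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot smd_sweep
#' @export
autoplot.smd_sweep <- function(object, metric = c("estimate", "bias", "se"),
                               corrected = FALSE, ...) {
  metric <- rlang::arg_match(metric)
  df <- dplyr::filter(object, .data$corrected == !!corrected)
  df$sd_pre_f <- factor(df$sd_pre)
  base <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, colour = .data$sd_pre_f,
                                           group = .data$sd_pre_f)) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "pre-post correlation r", colour = "sd_pre") +
    ggplot2::theme_minimal()
  switch(metric,
    estimate = base +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean_estimate)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$mean_estimate)) +
      ggplot2::labs(y = "mean estimate",
                    title = "Mean SMD estimate across the (r, sd_pre) grid"),
    bias = base +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_line(ggplot2::aes(y = .data$bias)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$bias)) +
      ggplot2::labs(y = "empirical bias", title = "Empirical bias"),
    se = base +
      ggplot2::geom_line(ggplot2::aes(y = .data$emp_se)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$emp_se)) +
      ggplot2::geom_line(
        data = dplyr::filter(df, !is.na(.data$formula_variance)),
        ggplot2::aes(y = sqrt(.data$formula_variance)), linetype = 3
      ) +
      ggplot2::labs(y = "standard error (solid: empirical, dotted: formula)",
                    title = "Estimator standard error")
  )
}

#' @rdname autoplot.smd_sweep
#' @param result An `smd_sweep` tibble.
#' @export
plot_sweep <- function(result, metric = c("estimate", "bias", "se"),
                       corrected = FALSE) {
  autoplot.smd_sweep(result, metric = metric, corrected = corrected)
}
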