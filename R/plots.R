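#' Plot a hazard / survival curve
#'
#' Step-style display of the per-period hazard probabilities and the
#' survivor function from [predict_curve()].
#'
#' @param object A `hazard_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hazard_curve
#' @export
autoplot.hazard_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("hazard", "survival"),
                              names_to = "quantity", values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$probability)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "period", y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot the baseline hazard of a fitted discrete-time model
#'
#' @param object A `dtsm_fit`.
#' @param profile Covariate profile passed to [predict_curve()]; defaults to
#'   all zeros (the baseline hazard).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dtsm_fit
#' @export
autoplot.dtsm_fit <- function(object, profile = NULL, ...) {
  autoplot(predict_curve(object, profile)) +
    ggplot2::ggtitle("Fitted discrete-time hazard and survival")
}

#' Forest plot of a mediation decomposition
#'
#' Point estimates with 95% Wald intervals for the direct effect, each
#' indirect path, the total indirect effect and the total effect.
#'
#' @param object A `mediation_decomposition`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mediation_decomposition
#' @export
autoplot.mediation_decomposition <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "effect on latent hazard (95% CI)", y = NULL,
                  title = sprintf("Effects of %s on %s",
                                  attr(object, "exposure"),
                                  attr(object, "outcome"))) +
    ggplot2::theme_minimal()
}
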