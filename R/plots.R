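#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot remission rates by index quartile
#'
#' Bar chart of the remission-proxy rate in each quartile of the index, the
#' package's standard descriptive comparison of the continuous score against
#' the binary prescription-gap proxy.
#'
#' @param object A `dhsi_quartiles` tibble from [quartile_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dhsi_quartiles
#' @export
autoplot.dhsi_quartiles <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$quartile,
                               y = 100 * .data$remission_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%",
                                                    100 * .data$remission_rate)),
                       vjust = -0.4, size = 3.2) +
    ggplot2::labs(x = "Index quartile", y = "Remission rate (%)",
                  title = "Remission proxy by health-state index quartile") +
    ggplot2::ylim(0, 105) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dhsi_quartiles
#' @param quartiles A `dhsi_quartiles` tibble.
#' @export
plot_remission_quartiles <- function(quartiles, ...) {
  autoplot.dhsi_quartiles(quartiles, ...)
}

#' Plot observed-versus-predicted index values for a fitted model
#'
#' @param object A `dhsi_model`.
#' @param flags Parameter flags the model is applied to.
#' @param dhsi The rank-derived index for the same episodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dhsi_model
#' @export
autoplot.dhsi_model <- function(object, flags, dhsi, ...) {
  pred <- predict_dhsi(object, flags)
  ggplot2::ggplot(tibble::tibble(ranked = dhsi, predicted = as.numeric(pred)),
                  ggplot2::aes(x = .data$ranked, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "firebrick") +
    ggplot2::labs(x = "Rank-derived index", y = "Model-predicted index") +
    ggplot2::theme_minimal()
}
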