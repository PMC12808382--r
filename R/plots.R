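#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time-activity curve
#'
#' Concentration against frame mid-time, with points sized nothing fancy —
#' frame durations are visible in the spacing of mid-times.
#'
#' @param object A `pet_tac`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pet_tac
#' @export
autoplot.pet_tac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid_time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (s)", y = "Concentration (kBq/mL)",
                  title = sprintf("%s time-activity curve",
                                  attr(object, "role") %||% "tissue"))
}

#' Plot a kinetic fit
#'
#' Observed frame values and the fitted one-tissue-compartment curve.
#'
#' @param object A `pet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pet_fit
#' @export
autoplot.pet_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fitted, c("observed", "fitted"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_time_s, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(data = df[df$series == "fitted", ]) +
    ggplot2::geom_point(data = df[df$series == "observed", ]) +
    ggplot2::labs(
      x = "Time (s)", y = "Concentration (kBq/mL)", colour = NULL,
      title = sprintf("1TCM fit: K1 = %.2f mL/100cm³/min, k2 = %.2f /min",
                      object$k1, object$k2)
    )
}

#' Bland-Altman plot
#'
#' Differences against pair means, with the bias line and the limits of
#' agreement (bias +/- 1.96 SD of the differences).
#'
#' @param x,y Paired measurements.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(x, y) {
  ba <- bland_altman(x, y)
  df <- tibble::tibble(mean = (x + y) / 2, diff = x - y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean of pair", y = "Difference",
                  title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                                  ba$bias, ba$loa_lower, ba$loa_upper))
}

#' @rdname virtual_rater_study
#' @param object A `pet_rater_study`.
#' @return `autoplot()`: ICC point estimates with confidence intervals per
#'   method and comparison.
#' @method autoplot pet_rater_study
#' @export
autoplot.pet_rater_study <- function(object, ...) {
  df <- object$agreement
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$icc,
                                   colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0.9, linetype = 3) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~design, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ICC(2,1)", colour = "VOI method")
}

#' @importFrom rlang .data
NULL
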