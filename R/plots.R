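#' Forest-style plot of the joint OR grid
#'
#' Odds ratios (log scale) by PRS quartile, colored by exposure status, with
#' Wald confidence intervals; the dashed line marks the reference OR of 1.
#'
#' @param object A `joint_or_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.joint_or_table <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      exposure = factor(ifelse(.data$exposed == 1,
                                               "exposed", "unexposed"),
                                        levels = c("unexposed", "exposed")))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$quartile), y = .data$or,
                                   color = .data$exposure)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "PRS quartile", y = "Odds ratio (log scale)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot RERI estimates per quartile
#'
#' Additive-interaction estimates with Delta-method confidence intervals;
#' the dashed line at 0 is exact additivity of excess risks.
#'
#' @param object A `reri_result` from [reri_inference()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reri_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$quartile), y = .data$reri)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "PRS quartile", y = "RERI") +
    ggplot2::theme_minimal()
}

#' Plot projected absolute risks by profile
#'
#' 30-year cumulative risk (percent) with bootstrap confidence intervals by
#' PRS quartile and exposure status.
#'
#' @param object An `absrisk_table` from [absolute_risk_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.absrisk_table <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      exposure = factor(ifelse(.data$exposed == 1,
                                               "exposed", "unexposed"),
                                        levels = c("unexposed", "exposed")))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$quartile),
                                   y = .data$risk, fill = .data$exposure)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = "PRS quartile", y = "30-year cumulative risk (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
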