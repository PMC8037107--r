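#' Plot strategy outcomes on the cost-effectiveness plane
#'
#' @param object A `cea_outcomes` tibble from [run_all()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_outcomes <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$qaly, y = .data$cost,
                               label = .data$strategy)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1) +
    ggplot2::labs(x = "QALYs (discounted)", y = "Lifetime cost (USD, discounted)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot a dominance classification with its efficiency frontier
#'
#' @param object A `cea_result` from [classify_dominance()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_result <- function(object, ...) {
  ggplot2::ggplot(object$strategies,
                  ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = object$frontier, linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$dominance), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy), vjust = -1) +
    ggplot2::labs(x = "QALYs (discounted)", y = "Lifetime cost (USD, discounted)",
                  colour = NULL, title = "Efficiency frontier") +
    ggplot2::theme_minimal()
}

#' Plot the PSA cost-effectiveness scatter
#'
#' @param object A `cea_psa` from [run_psa()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_psa <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$qaly, y = .data$cost,
                               colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::labs(x = "QALYs (discounted)", y = "Lifetime cost (USD, discounted)",
                  colour = NULL,
                  title = sprintf("PSA scatter (%d iterations)", object$n)) +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param object A `cea_ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_ceac <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "P(cost-effective)", colour = NULL,
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Plot age-dependent net monetary benefit
#'
#' @param object A `cea_age_sweep` tibble from [age_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cea_age_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$age, y = .data$nmb,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Starting age (years)", y = "Net monetary benefit (USD)",
                  colour = NULL, title = "Age-dependent net monetary benefit") +
    ggplot2::theme_minimal()
}
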