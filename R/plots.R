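#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars spanning the outcome (total cost difference, GBP mln) at
#' each item's lower and upper bound, ranked by range, with the base-case
#' outcome as a dashed reference line.
#'
#' @param object A `bcca_owsa` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcca_owsa <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(
      parameter = factor(path, levels = rev(path)),
      lo = pmin(outcome_low, outcome_high) / 1e6,
      hi = pmax(outcome_low, outcome_high) / 1e6
    )
  base <- attr(object, "base_outcome") / 1e6
  ggplot2::ggplot(d, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi, yend = parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "Total cost difference, NBI - HD-WLE (GBP mln)",
                  y = NULL, title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Budget-impact plot
#'
#' Yearly discounted expenditure per arm over the horizon.
#'
#' @param object A `bcca_budget` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcca_budget <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c(cost_nbi, cost_hdwle),
                        names_to = "arm", values_to = "cost") |>
    dplyr::mutate(arm = ifelse(arm == "cost_nbi", "NBI", "HD-WLE"))
  ggplot2::ggplot(d, ggplot2::aes(year, cost / 1e6, colour = arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Annual cost (GBP mln)", colour = NULL,
                  title = "Budget impact by year") +
    ggplot2::theme_minimal()
}

#' Cost-category comparison plot
#'
#' @param object A `bcca_cca` object.
#' @param ... Unused.
#' @return A ggplot object with one bar per cost category and arm.
#' @export
autoplot.bcca_cca <- function(object, ...) {
  d <- object$costs |>
    tidyr::pivot_longer(c(nbi, hdwle), names_to = "arm", values_to = "cost") |>
    dplyr::mutate(arm = ifelse(arm == "nbi", "NBI", "HD-WLE"))
  ggplot2::ggplot(d, ggplot2::aes(category, cost / 1e6, fill = arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Discounted cost (GBP mln)", fill = NULL,
                  title = "Cost-consequence analysis by category") +
    ggplot2::theme_minimal()
}
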