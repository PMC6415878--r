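#' Tidy a cost-consequence analysis
#'
#' One row per cost category and clinical outcome, with both arms and their
#' absolute/relative differences — the layout of the published
#' cost-consequence table, in raw units.
#'
#' @param x A `bcca_cca` object.
#' @param ... Unused.
#' @return A tibble with columns `block` (`costs`/`outcomes`), `item`,
#'   `nbi`, `hdwle`, `abs_diff`, `rel_diff`.
#' @export
tidy.bcca_cca <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(stats::setNames(x$costs, c("item", "nbi", "hdwle",
                                             "abs_diff", "rel_diff")),
                  block = "costs", .before = 1),
    dplyr::mutate(stats::setNames(x$outcomes, c("item", "nbi", "hdwle",
                                                "abs_diff", "rel_diff")),
                  block = "outcomes", .before = 1)
  )
}

#' One-line summary of a cost-consequence analysis
#'
#' @param x A `bcca_cca` object.
#' @param ... Unused.
#' @return A one-row tibble: totals per arm, difference, relative
#'   difference, horizon, perspective.
#' @export
glance.bcca_cca <- function(x, ...) {
  tibble::tibble(
    total_nbi = x$total_nbi,
    total_hdwle = x$total_hdwle,
    total_diff = x$total_diff,
    rel_diff = x$total_diff / x$total_hdwle,
    horizon_years = nrow(x$trace),
    perspective = x$params$economics$perspective,
    accuracy_level = x$params$economics$accuracy_level,
    long_term = x$params$economics$long_term
  )
}

#' @export
tidy.bcca_icer <- function(x, ...) {
  tibble::tibble(delta_cost = x$delta_cost, delta_effect = x$delta_effect,
                 ratio = x$ratio, label = x$label)
}

#' @export
tidy.bcca_scenario <- function(x, ...) {
  tibble::tibble(
    id = x$spec$id, description = x$spec$description,
    cost_nbi = x$cca$total_nbi, cost_hdwle = x$cca$total_hdwle,
    cost_difference = x$delta_cost, effect_difference = x$delta_effect,
    effect_unit = x$effect_unit, icer = x$icer$ratio, label = x$icer$label
  )
}

#' @export
glance.bcca_owsa <- function(x, ...) {
  tibble::tibble(
    base_outcome = attr(x, "base_outcome"),
    n_items = nrow(x),
    worst_outcome = max(pmax(x$outcome_low, x$outcome_high)),
    best_outcome = min(pmin(x$outcome_low, x$outcome_high)),
    all_cost_saving = all(x$outcome_low < 0 & x$outcome_high < 0)
  )
}
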