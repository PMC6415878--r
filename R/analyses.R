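#' Cost-consequence analysis of the two surveillance strategies
#'
#' Runs both comparator arms — the mixed NBI-adopting arm and the pure
#' HD-WLE arm — on a shared cohort trace and tabulates the disaggregated
#' discounted costs and undiscounted clinical event counts side by side,
#' with absolute (NBI - HD-WLE) and relative differences.
#'
#' @param params A `bcca_params` object; its scenario switches select
#'   perspective, accuracy level and long-term follow-up.
#' @return A `bcca_cca` object: list with tibbles `costs` (`category`,
#'   `nbi`, `hdwle`, `abs_diff`, `rel_diff`) and `outcomes` (same columns
#'   keyed by `outcome`), the two `bcca_arm_result`s, and the shared cohort
#'   trace. `rel_diff` is a fraction (-0.442, not -44.2%).
#' @examples
#' cca <- cost_consequence(default_parameters())
#' cca$outcomes
#' @export
cost_consequence <- function(params = default_parameters()) {
  nbi <- arm_result(params, "nbi")
  wle <- arm_result(params, "wle")
  pair <- function(a, b, key, val) {
    dplyr::full_join(
      stats::setNames(a, c(key, "nbi")),
      stats::setNames(b, c(key, "hdwle")),
      by = key
    ) |>
      dplyr::mutate(
        nbi = dplyr::coalesce(nbi, 0),
        hdwle = dplyr::coalesce(hdwle, 0),
        abs_diff = nbi - hdwle,
        rel_diff = ifelse(hdwle == 0, NA_real_, abs_diff / hdwle)
      )
  }
  costs <- pair(cost_breakdown(nbi)[, c("category", "cost")],
                cost_breakdown(wle)[, c("category", "cost")], "category")
  outcomes <- pair(nbi$consequences, wle$consequences, "outcome")
  structure(
    list(costs = costs, outcomes = outcomes,
         total_nbi = sum(costs$nbi), total_hdwle = sum(costs$hdwle),
         total_diff = sum(costs$nbi) - sum(costs$hdwle),
         nbi = nbi, hdwle = wle, trace = nbi$trace, params = params),
    class = "bcca_cca"
  )
}

#' @export
print.bcca_cca <- function(x, ...) {
  cat("<bcca_cca> cost-consequence analysis (",
      x$params$economics$perspective, " perspective, ",
      nrow(x$trace), "-year horizon)\n", sep = "")
  cat(sprintf("  total cost NBI:    GBP %12.1f mln\n", x$total_nbi / 1e6))
  cat(sprintf("  total cost HD-WLE: GBP %12.1f mln\n", x$total_hdwle / 1e6))
  cat(sprintf("  difference:        GBP %12.1f mln\n", x$total_diff / 1e6))
  invisible(x)
}

#' Budget-impact analysis
#'
#' Year-by-year projection of total payer expenditure per arm. The yearly
#' rows sum exactly to the cost-consequence grand totals.
#'
#' @param params A `bcca_params` object.
#' @param cca Optionally a precomputed [cost_consequence()] result on the
#'   same parameters (avoids re-running the engine).
#' @return A `bcca_budget` tibble with columns `year`, `population`,
#'   `cost_nbi`, `cost_hdwle`, `difference` (discounted GBP).
#' @export
budget_impact <- function(params = default_parameters(),
                          cca = cost_consequence(params)) {
  by_year <- function(res) {
    res$costs |>
      dplyr::group_by(year) |>
      dplyr::summarise(cost = sum(cost), .groups = "drop")
  }
  out <- cca$trace |>
    dplyr::select(year, population) |>
    dplyr::left_join(stats::setNames(by_year(cca$nbi), c("year", "cost_nbi")),
                     by = "year") |>
    dplyr::left_join(stats::setNames(by_year(cca$hdwle), c("year", "cost_hdwle")),
                     by = "year") |>
    dplyr::mutate(difference = cost_nbi - cost_hdwle)
  class(out) <- c("bcca_budget", class(out))
  attr(out, "total_population") <- cumulative_population(cca$trace)
  out
}

#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' @param delta_cost Incremental cost (GBP), intervention minus comparator.
#' @param delta_effect Incremental effect in natural units (detected lesions
#'   or avoided cancer cases; positive favours the intervention).
#' @return A `bcca_icer` list with `delta_cost`, `delta_effect`, `ratio`
#'   (GBP per unit effect, `NA` when the effect difference is zero) and
#'   `label`: `"dominant"` (cheaper, more effective),
#'   `"cost-saving-equal-effect"`, `"dominated"` (dearer, less effective),
#'   `"equivalent"` (both deltas zero), or `"tradeoff"`.
#' @examples
#' icer(-331.5e6, 1615) # about -205K GBP per avoided cancer case
#' @export
icer <- function(delta_cost, delta_effect) {
  label <- if (delta_cost == 0 && delta_effect == 0) {
    "equivalent"
  } else if (delta_cost < 0 && delta_effect > 0) {
    "dominant"
  } else if (delta_cost < 0 && delta_effect == 0) {
    "cost-saving-equal-effect"
  } else if (delta_cost > 0 && delta_effect < 0) {
    "dominated"
  } else {
    "tradeoff"
  }
  structure(
    list(delta_cost = delta_cost, delta_effect = delta_effect,
         ratio = if (delta_effect != 0) delta_cost / delta_effect else NA_real_,
         label = label),
    class = "bcca_icer"
  )
}

#' Format an ICER as thousands of GBP, 3 significant figures
#' @param x A `bcca_icer`.
#' @return Character, e.g. `"-205K GBP per unit effect"`, or the dominance
#'   label when no ratio is defined.
#' @export
format_icer <- function(x) {
  stopifnot(inherits(x, "bcca_icer"))
  if (is.na(x$ratio)) return(x$label)
  sprintf("%sK GBP per unit effect (%s)",
          format(signif(x$ratio / 1000, 3), big.mark = ","), x$label)
}

#' @export
print.bcca_icer <- function(x, ...) {
  cat("<bcca_icer> ", format_icer(x), "\n", sep = "")
  cat(sprintf("  delta cost:   GBP %.1f mln\n", x$delta_cost / 1e6))
  cat(sprintf("  delta effect: %.1f\n", x$delta_effect))
  invisible(x)
}

#' The six predefined scenarios
#'
#' Scenarios 1-4 adopt the NHS perspective (161,657 patients in year 1) and
#' cross diagnostic-accuracy level (per-patient vs per-lesion) with
#' long-term follow-up (off/on); scenarios 5-6 adopt the single-hospital
#' perspective (649 patients in year 1), short-term only.
#'
#' @return A tibble with columns `id`, `perspective`, `accuracy_level`,
#'   `long_term`, `description`.
#' @export
scenario_grid <- function() {
  tibble::tibble(
    id = 1:6,
    perspective = c("NHS", "NHS", "NHS", "NHS", "hospital", "hospital"),
    accuracy_level = c("per_patient", "per_patient", "per_lesion",
                       "per_lesion", "per_patient", "per_lesion"),
    long_term = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    description = c(
      "NHS, per-patient accuracy, diagnostic phase only",
      "NHS, per-patient accuracy, long-term follow-up",
      "NHS, per-lesion accuracy, diagnostic phase only",
      "NHS, per-lesion accuracy, long-term follow-up",
      "Hospital, per-patient accuracy, diagnostic phase only",
      "Hospital, per-lesion accuracy, diagnostic phase only"
    )
  )
}

#' Run one scenario
#'
#' Wires the scenario's accuracy level, perspective and long-term switch
#' into the pipeline and computes the cost difference, the effect difference
#' (detected lesions for per-lesion scenarios without follow-up; avoided
#' cancer cases for per-lesion scenarios with follow-up; zero under equal
#' per-patient accuracy) and the resulting ICER.
#'
#' @param id Scenario id 1-6, or a one-row spec like a [scenario_grid()]
#'   row.
#' @param params Base `bcca_params`; the scenario switches are overridden.
#' @return A `bcca_scenario` list with the spec, the [cost_consequence()]
#'   result, `delta_cost`, `delta_effect`, `effect_unit` and `icer`.
#' @export
run_scenario <- function(id, params = default_parameters()) {
  grid <- scenario_grid()
  spec <- if (is.numeric(id)) {
    if (!id %in% grid$id)
      stop("unknown scenario id ", id, " (defined: 1-6)", call. = FALSE)
    grid[grid$id == id, ]
  } else {
    id
  }
  if (spec$perspective == "hospital" && isTRUE(spec$long_term))
    stop("invalid scenario: long-term follow-up is not defined for the hospital perspective",
         call. = FALSE)
  p <- apply_override(params, "economics.perspective", spec$perspective)
  p <- apply_override(p, "economics.accuracy_level", spec$accuracy_level)
  p <- apply_override(p, "economics.long_term", spec$long_term)
  cca <- cost_consequence(p)
  getcount <- function(res, what) {
    i <- match(what, cca$outcomes$outcome)
    if (is.na(i)) NA_real_ else cca$outcomes[[res]][i]
  }
  if (spec$accuracy_level == "per_patient") {
    delta_effect <- 0
    effect_unit <- "none (equal accuracy)"
  } else if (isTRUE(spec$long_term)) {
    delta_effect <- getcount("hdwle", "incident_eac") - getcount("nbi", "incident_eac")
    effect_unit <- "avoided cancer cases"
  } else {
    delta_effect <- getcount("nbi", "detected_lesions") - getcount("hdwle", "detected_lesions")
    effect_unit <- "incremental detected lesions"
  }
  structure(
    list(spec = spec, cca = cca,
         delta_cost = cca$total_diff,
         delta_effect = delta_effect,
         effect_unit = effect_unit,
         icer = icer(cca$total_diff, delta_effect)),
    class = "bcca_scenario"
  )
}

#' @export
print.bcca_scenario <- function(x, ...) {
  cat("<bcca_scenario> ", x$spec$id, ": ", x$spec$description, "\n", sep = "")
  cat(sprintf("  cost difference: GBP %.1f mln\n", x$delta_cost / 1e6))
  cat("  effect difference: ", format(round(x$delta_effect, 1)),
      " ", x$effect_unit, "\n", sep = "")
  cat("  ", format_icer(x$icer), "\n", sep = "")
  invisible(x)
}

#' Run all six scenarios
#'
#' @param params Base `bcca_params`.
#' @return A tibble with one row per scenario: id, switches, cost per arm,
#'   cost difference, effect difference and unit, ICER ratio and label.
#' @export
run_all_scenarios <- function(params = default_parameters()) {
  purrr::map_dfr(scenario_grid()$id, function(i) {
    s <- run_scenario(i, params)
    tibble::tibble(
      id = s$spec$id,
      description = s$spec$description,
      cost_nbi = s$cca$total_nbi,
      cost_hdwle = s$cca$total_hdwle,
      cost_difference = s$delta_cost,
      effect_difference = s$delta_effect,
      effect_unit = s$effect_unit,
      icer = s$icer$ratio,
      label = s$icer$label
    )
  })
}
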