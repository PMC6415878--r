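#' Default one-way sensitivity analysis items
#'
#' Every input is varied by a relative +/-10% around its default, except the
#' discount rate, which runs from 2.0% to 5.0%. Probabilities whose +10%
#' bound would exceed 1 are clipped to 1 (with a warning at run time).
#' The diagnostic-accuracy item would properly use the 95% confidence
#' interval of the source meta-analysis; those bounds are not part of the
#' default input set, so accuracy also defaults to +/-10% — supply your own
#' bounds to override.
#'
#' @param params A `bcca_params` object.
#' @return A tibble with columns `path`, `low`, `high`.
#' @export
default_owsa_items <- function(params = default_parameters()) {
  rel <- function(path) {
    v <- get_parameter(params, path)
    tibble::tibble(path = path, low = v * 0.9, high = v * 1.1)
  }
  items <- dplyr::bind_rows(
    rel("epidemiology.n_year1"),
    rel("epidemiology.annual_growth"),
    rel("accuracy.per_patient_sens"),
    rel("accuracy.per_patient_spec"),
    rel("procedure.biopsies_nbi"),
    rel("procedure.biopsies_wle"),
    rel("procedure.endo_ae_nbi.perforation"),
    rel("procedure.endo_ae_wle.perforation"),
    rel("procedure.endo_ae_nbi.bleeding"),
    rel("procedure.endo_ae_wle.bleeding"),
    rel("procedure.treat_ae.stricture"),
    rel("procedure.eradication_rate"),
    rel("costs.tariff_endoscopy"),
    rel("costs.tariff_emr_rfa"),
    rel("costs.cost_per_biopsy"),
    rel("costs.ae_costs.perforation"),
    rel("costs.ae_costs.bleeding"),
    rel("equipment.unit_cost_system"),
    rel("equipment.unit_cost_scope"),
    tibble::tibble(path = "economics.discount_rate", low = 0.02, high = 0.05)
  )
  items
}

#' Deterministic one-way sensitivity analysis (tornado)
#'
#' Re-runs the full cost-consequence pipeline at the lower and upper bound
#' of each item, holding everything else at base, and ranks items by the
#' range of the outcome (total discounted cost difference, NBI minus
#' HD-WLE). The input parameter set is never modified.
#'
#' @param params Base `bcca_params`.
#' @param items Tibble of `path`, `low`, `high` rows;
#'   [default_owsa_items()] by default. All paths are validated before any
#'   model run.
#' @return A `bcca_owsa` tibble, one row per item, ranked by decreasing
#'   `range`: `path`, `low`, `high`, `outcome_low`, `outcome_high`,
#'   `outcome_base`, `range`.
#' @export
owsa <- function(params = default_parameters(), items = default_owsa_items(params)) {
  valid <- parameter_paths(params)
  bad <- setdiff(items$path, valid)
  if (length(bad))
    stop("unknown parameter path(s): ", paste(bad, collapse = ", "), call. = FALSE)
  clip_prob <- function(path, v) {
    # only probabilities/shares live in [0,1]; detect by base value and section
    base <- get_parameter(params, path)
    is_prob <- base <= 1 &&
      grepl("sens|spec|rate|share|growth|ae", path) &&
      !grepl("cost|tariff", path)
    if (is_prob && v > 1) {
      warning("bound for ", path, " clipped to 1", call. = FALSE)
      return(1)
    }
    v
  }
  base_outcome <- cost_consequence(params)$total_diff
  run_at <- function(path, value) {
    cost_consequence(apply_override(params, path, clip_prob(path, value)))$total_diff
  }
  out <- items |>
    dplyr::mutate(
      outcome_low = purrr::map2_dbl(path, low, run_at),
      outcome_high = purrr::map2_dbl(path, high, run_at),
      outcome_base = base_outcome,
      range = abs(outcome_high - outcome_low)
    ) |>
    dplyr::arrange(dplyr::desc(range))
  class(out) <- c("bcca_owsa", class(out))
  attr(out, "base_outcome") <- base_outcome
  out
}

#' Equal adverse-event-rate sensitivity analysis
#'
#' Re-runs the model assuming endoscopy adverse-event rates do not depend on
#' the number of biopsies taken, i.e. the NBI arm experiences the same
#' per-procedure rates as HD-WLE. Because adverse-event costs enter the
#' total additively, the new difference equals the base difference minus the
#' adverse-event cost-difference component — an identity this function also
#' returns the ingredients of.
#'
#' @param params A `bcca_params` object.
#' @return A list with `base_diff`, `ae_component` (the adverse-events
#'   category difference in the base run), `equal_ae_diff` (total difference
#'   with equalised rates), and `identity_residual`
#'   (`equal_ae_diff - (base_diff - ae_component)`, ~0).
#' @export
equal_ae_analysis <- function(params = default_parameters()) {
  base <- cost_consequence(params)
  ae_row <- base$costs[base$costs$category == "adverse_events", ]
  ae_component <- ae_row$abs_diff
  p <- params
  for (ev in names(params$procedure$endo_ae_wle)) {
    p <- apply_override(p, paste0("procedure.endo_ae_nbi.", ev),
                        params$procedure$endo_ae_wle[[ev]])
  }
  equal <- cost_consequence(p)
  list(
    base_diff = base$total_diff,
    ae_component = ae_component,
    equal_ae_diff = equal$total_diff,
    identity_residual = equal$total_diff - (base$total_diff - ae_component)
  )
}
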