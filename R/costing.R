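#' Staff micro-cost of one endoscopy
#'
#' Sum of hourly staff rates times per-procedure staff times for one
#' technique. Nurse non-contact time is proportional to the number of
#' biopsies taken, which is why the NBI procedure is cheaper to staff.
#'
#' @param params A `bcca_params` object.
#' @param technique `"nbi"` or `"wle"` (technique level, not arm level: the
#'   mixed NBI arm blends the two by market share).
#' @return GBP per procedure.
#' @examples
#' staff_cost_per_procedure(default_parameters(), "wle") # 186.99
#' @export
staff_cost_per_procedure <- function(params, technique = c("nbi", "wle")) {
  technique <- match.arg(technique)
  times <- if (technique == "nbi") params$costs$staff_times_nbi else params$costs$staff_times_wle
  rates <- params$costs$staff_rates
  sum(unlist(rates)[names(times)] * unlist(times))
}

#' Histopathology cost over the horizon
#'
#' Biopsies are billed at a flat unit cost; money is discounted, biopsy
#' counts are not.
#'
#' @param biopsies_per_year Numeric vector of biopsies taken each year.
#' @param cost_per_biopsy GBP per biopsy.
#' @param factors Discount factors, same length.
#' @return Discounted GBP total.
#' @export
histopathology_cost <- function(biopsies_per_year, cost_per_biopsy, factors) {
  stopifnot(length(biopsies_per_year) == length(factors))
  sum(biopsies_per_year * cost_per_biopsy * factors)
}

#' Adverse-event management cost over the horizon
#'
#' @param profile A tibble with columns `year`, `event`, `count` (as built
#'   by the pathway for each model year).
#' @param ae_costs Named list of unit costs (`stricture`, `bleeding`,
#'   `perforation`).
#' @param factors Discount factors indexed by year.
#' @return Discounted GBP total.
#' @export
ae_cost_total <- function(profile, ae_costs, factors) {
  if (nrow(profile) == 0) return(0)
  unit <- unlist(ae_costs)[profile$event]
  sum(profile$count * unit * factors[profile$year])
}

# Per-procedure expected endoscopy AE management cost for an arm
endo_ae_unit_cost <- function(params, arm) {
  inp <- arm_inputs(params, arm)
  sum(unlist(inp$endo_ae) * unlist(params$costs$ae_costs)[names(inp$endo_ae)])
}

# Per-treated-patient expected treatment AE management cost
treat_ae_unit_cost <- function(params) {
  tr <- params$procedure$treat_ae
  sum(unlist(tr) * unlist(params$costs$ae_costs)[names(tr)])
}

#' Capital-equipment cost per year
#'
#' One-off purchases in the NBI arm upgrade the Olympus-installed estate:
#' non-NBI-capable systems are replaced, standard-definition scopes are
#' replaced with HD scopes, and half of the endoscopists receive two days of
#' training. Purchases are amortized as equal annual charges over the
#' equipment lifetime and then discounted like any other cost. Both arms
#' accrue annual scope replacement for wear (the NBI arm only on the share
#' of the estate it did not just upgrade). Maintenance contracts are a
#' hospital-perspective cost only.
#'
#' @param params A `bcca_params` object.
#' @param arm `"nbi"` or `"wle"`.
#' @param perspective `"NHS"` (national estate) or `"hospital"` (single
#'   hospital).
#' @param factors Discount factors for the horizon.
#' @return A tibble with columns `year` and `cost` (discounted GBP).
#' @export
capital_equipment_cost <- function(params, arm = c("nbi", "wle"),
                                   perspective = params$economics$perspective,
                                   factors = discount_factors(
                                     params$economics$discount_rate,
                                     params$epidemiology$horizon_years)) {
  arm <- match.arg(arm)
  eq <- params$equipment
  shares <- unlist(eq[c("olympus_share", "nbi_capable_share",
                        "hd_scope_share", "trained_share")])
  if (any(shares < 0 | shares > 1))
    stop("equipment shares must be in [0,1]", call. = FALSE)
  hospitals <- if (perspective == "hospital") 1 else eq$hospitals
  rooms <- hospitals * eq$rooms_per_hospital
  scopes <- rooms * eq$scopes_per_room
  years <- length(factors)

  if (arm == "nbi") {
    systems_upgrade <- hospitals * eq$olympus_share * (1 - eq$nbi_capable_share) *
      eq$rooms_per_hospital * eq$unit_cost_system
    scope_upgrade <- hospitals * eq$olympus_share * eq$rooms_per_hospital *
      eq$scopes_per_room * (1 - eq$hd_scope_share) * eq$unit_cost_scope
    training <- hospitals * eq$olympus_share * eq$endoscopists_per_hospital *
      eq$trained_share * eq$training_days_nbi * eq$training_cost_per_day_nbi
    replacement_share <- 1 - eq$olympus_share
    maint <- rooms * eq$maintenance_system_nbi + scopes * eq$maintenance_scope_nbi
  } else {
    systems_upgrade <- 0
    scope_upgrade <- 0
    training <- hospitals * eq$olympus_share * eq$endoscopists_per_hospital *
      eq$trained_share * eq$training_days_wle * eq$training_cost_per_day_wle
    replacement_share <- 1
    maint <- rooms * eq$maintenance_system_wle + scopes * eq$maintenance_scope_wle
  }
  oneoff <- systems_upgrade + scope_upgrade + training
  amort <- pmin(eq$amortization_years, years)
  annual <- numeric(years)
  annual[seq_len(amort)] <- oneoff / eq$amortization_years
  annual <- annual + scopes * eq$replacement_rate * eq$unit_cost_scope * replacement_share
  if (perspective == "hospital") annual <- annual + maint
  tibble::tibble(year = seq_len(years), cost = annual * factors)
}

#' Full cost and consequence engine for one arm
#'
#' Runs one comparator arm through the cohort trace, decision tree, (when
#' enabled) the long-term Markov follow-up, and the costing rules of the
#' configured perspective. Under the NHS perspective, endoscopy and
#' treatment are booked at their national tariffs (staff and consumable
#' micro-costs are covered under tariff), plus histopathology, adverse-event
#' management and capital costs. Under the hospital perspective, endoscopy
#' and treatment are micro-costed (staff time plus consumables), tariffs are
#' booked as income, and equipment maintenance is added to capital.
#'
#' Money is discounted annually; event counts are reported undiscounted.
#'
#' @param params A `bcca_params` object; the scenario switches
#'   (`economics$perspective`, `economics$accuracy_level`,
#'   `economics$long_term`) select the pipeline wiring.
#' @param arm `"nbi"` (mixed 84/16 technology arm) or `"wle"` (pure
#'   HD-WLE).
#' @return A `bcca_arm_result` list with elements `costs` (tibble `year`,
#'   `category`, `cost`, discounted GBP), `income` (tibble or `NULL`),
#'   `consequences` (tibble `outcome`, `count`, undiscounted), `trace`,
#'   and `arm`.
#' @export
arm_result <- function(params, arm = c("nbi", "wle")) {
  arm <- match.arg(arm)
  persp <- params$economics$perspective
  long_term <- isTRUE(params$economics$long_term)
  if (long_term && persp == "hospital")
    stop("long-term follow-up is defined for the NHS perspective only",
         call. = FALSE)
  inp <- arm_inputs(params, arm)
  trace <- cohort_trace(params, persp)
  years <- nrow(trace)
  f <- trace$discount_factor
  pop <- trace$population_exact
  mix <- disease_mix(params$epidemiology$parasa)
  hist <- if (isTRUE(params$accuracy$hist_layer_enabled)) {
    list(sens = params$accuracy$hist_sens, spec = params$accuracy$hist_spec)
  } else NULL
  co <- params$costs
  forceps_unit <- co$consumables$forceps_pack / co$consumables$forceps_pack_units
  snare_unit <- co$consumables$snare_pack / co$consumables$snare_pack_units
  staff_endo <- blended_biopsies(inp$share,
                                 staff_cost_per_procedure(params, "nbi"),
                                 staff_cost_per_procedure(params, "wle"))

  # -- index (diagnostic) phase, one classification per entry year ----------
  cls_total <- classify_patients(sum(pop), mix, inp$sens, inp$spec, hist)
  tc_total <- treatment_counts(cls_total, params$procedure$eradication_rate)
  treated_frac <- tc_total$treated / sum(pop)
  treated_y <- pop * treated_frac
  biopsies_y <- pop * inp$biopsies
  ae_y <- purrr::map_dfr(seq_len(years), function(t) {
    dplyr::mutate(
      adverse_events(params, arm, cohort = pop[t], treated = treated_y[t],
                     biopsies = biopsies_y[t]),
      year = t
    )
  })

  endo_unit <- if (persp == "NHS") co$tariff_endoscopy else staff_endo + forceps_unit
  treat_unit <- if (persp == "NHS") co$tariff_emr_rfa else snare_unit

  cost_rows <- list(
    tibble::tibble(year = seq_len(years), category = "endoscopy_staff_overheads",
                   cost = pop * endo_unit * f),
    tibble::tibble(year = seq_len(years), category = "treatment_staff_overheads",
                   cost = treated_y * treat_unit * f),
    tibble::tibble(year = seq_len(years), category = "histopathology",
                   cost = biopsies_y * co$cost_per_biopsy * f),
    ae_y |>
      dplyr::group_by(year) |>
      dplyr::summarise(
        cost = sum(count * unlist(co$ae_costs)[event]), .groups = "drop") |>
      dplyr::mutate(category = "adverse_events", cost = cost * f[year]) |>
      dplyr::select(year, category, cost),
    capital_equipment_cost(params, arm, persp, f) |>
      dplyr::mutate(category = "capital_equipment") |>
      dplyr::select(year, category, cost)
  )

  income <- NULL
  if (persp == "hospital") {
    income <- tibble::tibble(
      year = seq_len(years),
      income = (pop * co$tariff_endoscopy + treated_y * co$tariff_emr_rfa) * f
    )
  }

  # undiscounted clinical event counts over the whole horizon
  ae_totals <- ae_y |>
    dplyr::group_by(event) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  cons <- tibble::tibble(
    outcome = c("correctly_identified", "successful_eradications", "biopsies",
                "strictures", "bleedings", "perforations"),
    count = c(correctly_identified(cls_total),
              tc_total$reported_eradications,
              sum(biopsies_y),
              ae_totals$count[match(c("stricture", "bleeding", "perforation"),
                                    ae_totals$event)])
  )
  if (params$economics$accuracy_level == "per_lesion") {
    dys_frac <- 1 - mix$fraction[1]
    lesions <- sum(pop) * dys_frac * params$accuracy$lesions_per_patient * inp$sens
    cons <- dplyr::bind_rows(cons,
      tibble::tibble(outcome = "detected_lesions", count = lesions))
  }

  longterm <- NULL
  if (long_term) {
    # each entry-year cohort is followed to the end of the horizon; cycle c
    # after entry in year y falls in calendar year y + ceiling(c/2) - 1
    endo_surv_unit <- endo_unit + inp$biopsies * co$cost_per_biopsy +
      endo_ae_unit_cost(params, arm)
    treat_surv_unit <- treat_unit + treat_ae_unit_cost(params)
    lt_rows <- list()
    inc_eac <- 0
    surv_endo <- 0
    surv_treat <- 0
    surv_biopsies <- 0
    for (y in seq_len(years)) {
      cls_y <- classify_patients(pop[y], mix, inp$sens, inp$spec, hist)
      n_cycles <- 2 * (years - y + 1) - 2
      if (n_cycles < 1) next
      lt <- long_term_trace(cls_y, params, arm, cycles = n_cycles)
      pc <- lt$per_cycle
      pc$cal_year <- y + ceiling(pc$cycle / 2) - 1
      fy <- f[pc$cal_year]
      lt_rows[[y]] <- dplyr::bind_rows(
        tibble::tibble(year = pc$cal_year, category = "endoscopy_staff_overheads",
                       cost = pc$endoscopies * endo_surv_unit * fy),
        tibble::tibble(year = pc$cal_year, category = "treatment_staff_overheads",
                       cost = pc$treatments * treat_surv_unit * fy),
        tibble::tibble(year = pc$cal_year, category = "cancer_management",
                       cost = pc$managed_eac * co$cancer_cost_per_year / 2 * fy)
      )
      inc_eac <- inc_eac + lt$incident_eac
      surv_endo <- surv_endo + lt$endoscopies
      surv_treat <- surv_treat + lt$treatments
      surv_biopsies <- surv_biopsies + lt$endoscopies * inp$biopsies
    }
    lt_costs <- dplyr::bind_rows(lt_rows) |>
      dplyr::group_by(year, category) |>
      dplyr::summarise(cost = sum(cost), .groups = "drop")
    cost_rows <- c(cost_rows, list(lt_costs))
    cons <- dplyr::bind_rows(cons, tibble::tibble(
      outcome = c("incident_eac", "surveillance_endoscopies",
                  "surveillance_treatments", "surveillance_biopsies"),
      count = c(inc_eac, surv_endo, surv_treat, surv_biopsies)
    ))
    longterm <- list(incident_eac = inc_eac)
  }

  costs <- dplyr::bind_rows(cost_rows) |>
    dplyr::group_by(year, category) |>
    dplyr::summarise(cost = sum(cost), .groups = "drop") |>
    dplyr::arrange(year, category)

  structure(
    list(arm = arm, costs = costs, income = income, consequences = cons,
         trace = trace, classification = cls_total, longterm = longterm),
    class = "bcca_arm_result"
  )
}

#' Cost breakdown by category for one arm
#'
#' @param result A `bcca_arm_result` from [arm_result()].
#' @return A tibble `category`, `cost` (discounted GBP) plus a
#'   `grand_total` attribute.
#' @export
cost_breakdown <- function(result) {
  out <- result$costs |>
    dplyr::group_by(category) |>
    dplyr::summarise(cost = sum(cost), .groups = "drop")
  attr(out, "grand_total") <- sum(out$cost)
  out
}
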