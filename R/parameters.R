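#' Default model parameters
#'
#' Builds the complete default input set of the model: epidemiology of the
#' surveilled population, diagnostic accuracy (per-patient and per-lesion),
#' procedural inputs (biopsies, adverse-event rates, eradication rate),
#' economic settings (discounting, perspective, NBI market share), unit costs
#' (tariffs, histopathology, staff, consumables, adverse events, cancer
#' management) and the capital-equipment plan. All probabilities and shares
#' are stored as fractions, never percentages; the report layer formats them.
#' The disease-state mix is stored as the underlying integer cohort counts
#' (2,696 patients of whom 751 LG, 106 HG, 48 EAC) rather than the rounded
#' percentages, because downstream event counts depend on the exact fractions.
#'
#' @return A `bcca_params` object: a validated nested list with sections
#'   `epidemiology`, `accuracy`, `procedure`, `economics`, `costs`,
#'   `equipment`.
#' @examples
#' p <- default_parameters()
#' p$epidemiology$n_year1
#' @export
default_parameters <- function() {
  p <- list(
    epidemiology = list(
      n_year1         = 161657,
      annual_growth   = 0.20,
      horizon_years   = 7L,
      hospital_cohort = 649,
      parasa = list(total = 2696L, dysplastic = 905L,
                    lg = 751L, hg = 106L, eac = 48L)
    ),
    accuracy = list(
      per_patient_sens    = 0.942,
      per_patient_spec    = 0.944,
      per_lesion_sens_nbi = 0.890,
      per_lesion_spec_nbi = 0.800,
      per_lesion_sens_wle = 0.791,
      per_lesion_spec_wle = 0.810,
      hist_sens           = 1.0,
      hist_spec           = 0.629,
      hist_layer_enabled  = FALSE,
      lesions_per_patient = 1
    ),
    procedure = list(
      biopsies_nbi = 3.6,
      biopsies_wle = 7.6,
      endo_ae_nbi  = list(stricture = 0.0001, perforation = 0.014, bleeding = 0.002),
      endo_ae_wle  = list(stricture = 0.0001, perforation = 0.030, bleeding = 0.005),
      treat_ae     = list(stricture = 0.335, perforation = 0.013, bleeding = 0.075),
      eradication_rate  = 0.949,
      ae_exposure_basis = "per_procedure"
    ),
    economics = list(
      discount_rate   = 0.035,
      perspective     = "NHS",
      market_share_nbi = 0.84,
      accuracy_level  = "per_patient",
      long_term       = FALSE
    ),
    costs = list(
      tariff_endoscopy = 517,
      tariff_emr_rfa   = 2101,
      cost_per_biopsy  = 82,
      ae_costs = list(stricture = 392, bleeding = 392, perforation = 2852),
      cancer_cost_per_year = 7647,
      staff_rates = list(admin = 23, nurse_noncontact = 41, consultant_ba = 142,
                         nurse_contact = 100, consultant_during = 142),
      staff_times_nbi = list(admin = 0.30, nurse_noncontact = 0.42, consultant_ba = 0.50,
                             nurse_contact = 0.30, consultant_during = 0.30),
      staff_times_wle = list(admin = 0.30, nurse_noncontact = 0.89, consultant_ba = 0.50,
                             nurse_contact = 0.30, consultant_during = 0.30),
      consumables = list(snare_pack = 240, snare_pack_units = 20,
                         forceps_pack = 210, forceps_pack_units = 10)
    ),
    equipment = list(
      hospitals               = 249,
      rooms_per_hospital      = 3.25,
      endoscopists_per_hospital = 3.25,
      scopes_per_room         = 4,
      olympus_share           = 0.84,
      nbi_capable_share       = 0.83,
      hd_scope_share          = 0.40,
      trained_share           = 0.50,
      replacement_rate        = 0.029,
      unit_cost_system        = 41316,
      unit_cost_scope         = 30487,
      training_cost_per_day_nbi = 1136,
      training_cost_per_day_wle = 795,
      training_days_nbi       = 2,
      training_days_wle       = 0,
      maintenance_system_nbi  = 4590,
      maintenance_system_wle  = 4527,
      maintenance_scope_nbi   = 4285,
      maintenance_scope_wle   = 4089,
      amortization_years      = 7
    )
  )
  validate_parameters(new_bcca_params(p))
}

new_bcca_params <- function(x) structure(x, class = "bcca_params")

#' @export
print.bcca_params <- function(x, ...) {
  cat("<bcca_params> Barrett's surveillance model inputs\n")
  cat("  cohort: ", format(x$epidemiology$n_year1, big.mark = ","),
      " patients/yr, +", x$epidemiology$annual_growth * 100, "%/yr over ",
      x$epidemiology$horizon_years, " years\n", sep = "")
  cat("  perspective: ", x$economics$perspective,
      "; accuracy level: ", x$economics$accuracy_level,
      "; long-term: ", x$economics$long_term, "\n", sep = "")
  cat("  use tidy() for the full path/value listing\n")
  invisible(x)
}

# Invariant checks. Errors name the offending field/invariant.
validate_parameters <- function(p) {
  stop_invalid <- function(msg) stop("invalid parameters: ", msg, call. = FALSE)
  e <- p$epidemiology
  if (!is.numeric(e$n_year1) || e$n_year1 <= 0)
    stop_invalid("epidemiology.n_year1 must be > 0")
  if (e$annual_growth < 0) stop_invalid("epidemiology.annual_growth must be >= 0")
  if (e$horizon_years < 1) stop_invalid("epidemiology.horizon_years must be >= 1")
  pa <- e$parasa
  if (pa$lg + pa$hg + pa$eac != pa$dysplastic)
    stop_invalid("epidemiology.parasa: lg + hg + eac must equal dysplastic")
  if (pa$dysplastic > pa$total)
    stop_invalid("epidemiology.parasa: dysplastic must not exceed total")
  probs <- c(
    unlist(p$accuracy[c("per_patient_sens", "per_patient_spec",
                        "per_lesion_sens_nbi", "per_lesion_spec_nbi",
                        "per_lesion_sens_wle", "per_lesion_spec_wle",
                        "hist_sens", "hist_spec")]),
    unlist(p$procedure$endo_ae_nbi), unlist(p$procedure$endo_ae_wle),
    unlist(p$procedure$treat_ae), eradication_rate = p$procedure$eradication_rate,
    market_share_nbi = p$economics$market_share_nbi,
    unlist(p$equipment[c("olympus_share", "nbi_capable_share",
                         "hd_scope_share", "trained_share")])
  )
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop_invalid(paste0("probability/share out of [0,1]: ",
                        paste(names(probs)[bad], collapse = ", ")))
  if (p$procedure$biopsies_nbi > p$procedure$biopsies_wle)
    stop_invalid("procedure.biopsies_nbi must be <= procedure.biopsies_wle")
  if (!p$procedure$ae_exposure_basis %in% c("per_procedure", "per_biopsy", "per_treated"))
    stop_invalid("procedure.ae_exposure_basis must be one of per_procedure, per_biopsy, per_treated")
  if (p$economics$discount_rate < 0) stop_invalid("economics.discount_rate must be >= 0")
  if (!p$economics$perspective %in% c("NHS", "hospital"))
    stop_invalid("economics.perspective must be 'NHS' or 'hospital'")
  if (!p$economics$accuracy_level %in% c("per_patient", "per_lesion"))
    stop_invalid("economics.accuracy_level must be 'per_patient' or 'per_lesion'")
  money <- unlist(p$costs[c("tariff_endoscopy", "tariff_emr_rfa", "cost_per_biopsy",
                            "cancer_cost_per_year")])
  money <- c(money, unlist(p$costs$ae_costs), unlist(p$costs$staff_rates),
             unlist(p$costs$consumables),
             unlist(p$equipment[c("unit_cost_system", "unit_cost_scope")]))
  if (any(money < 0)) stop_invalid("all unit costs must be >= 0")
  counts <- unlist(p$equipment[c("hospitals", "rooms_per_hospital",
                                 "endoscopists_per_hospital", "scopes_per_room")])
  if (any(counts <= 0)) stop_invalid("equipment counts must be > 0")
  if (p$equipment$amortization_years < 1)
    stop_invalid("equipment.amortization_years must be >= 1")
  p
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a YAML document with any subset of the sections
#' `epidemiology` / `accuracy` / `procedure` / `economics` / `costs` /
#' `equipment` and merges it onto the defaults, so an empty document (or
#' `path = NULL`) yields exactly [default_parameters()]. Every supplied field
#' must already exist in the default set; unknown fields are a configuration
#' error naming the field. The merged set is validated before it is returned.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional nested list applied after the file, same rules.
#' @return A validated `bcca_params` object.
#' @seealso [write_parameters()] for the serialising counterpart;
#'   [apply_override()] for single dotted-path edits.
#' @export
load_parameters <- function(path = NULL, overrides = list()) {
  p <- unclass(default_parameters())
  merge_in <- function(base, new, prefix = "") {
    for (nm in names(new)) {
      full <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (!nm %in% names(base))
        stop("configuration error: unknown field '", full, "'", call. = FALSE)
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        if (!is.list(new[[nm]]))
          stop("configuration error: field '", full, "' must be a section", call. = FALSE)
        base[[nm]] <- merge_in(base[[nm]], new[[nm]], full)
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) {
    doc <- yaml::read_yaml(path)
    if (!is.null(doc)) p <- merge_in(p, doc)
  }
  if (length(overrides)) p <- merge_in(p, overrides)
  validate_parameters(new_bcca_params(p))
}

#' Serialise a parameter set to YAML
#'
#' Round-trip safe: `load_parameters(write_parameters(p, f))` reproduces `p`
#' exactly.
#'
#' @param params A `bcca_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "bcca_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' List all parameter paths
#'
#' @param params A `bcca_params` object.
#' @return Character vector of dotted leaf paths, e.g.
#'   `"costs.cost_per_biopsy"`.
#' @export
parameter_paths <- function(params = default_parameters()) {
  walk <- function(x, prefix) {
    out <- character()
    for (nm in names(x)) {
      full <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.list(x[[nm]]) && !is.null(names(x[[nm]]))) {
        out <- c(out, walk(x[[nm]], full))
      } else {
        out <- c(out, full)
      }
    }
    out
  }
  walk(unclass(params), "")
}

#' Override a single parameter by dotted path
#'
#' Pure: returns a new parameter set differing only in the named field, and
#' re-validates; the input is unchanged. This is the primitive the one-way
#' sensitivity analysis is built on.
#'
#' @param params A `bcca_params` object.
#' @param path Dotted path such as `"costs.cost_per_biopsy"`.
#' @param value Replacement scalar.
#' @return A new validated `bcca_params` object.
#' @examples
#' p <- apply_override(default_parameters(), "costs.cost_per_biopsy", 90.2)
#' p$costs$cost_per_biopsy
#' @export
apply_override <- function(params, path, value) {
  stopifnot(inherits(params, "bcca_params"))
  valid <- parameter_paths(params)
  if (!path %in% valid) {
    stop("unknown parameter path '", path, "'. Valid paths:\n  ",
         paste(valid, collapse = "\n  "), call. = FALSE)
  }
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  p <- unclass(params)
  p[[keys]] <- value
  validate_parameters(new_bcca_params(p))
}

#' Fetch a parameter by dotted path
#' @param params A `bcca_params` object.
#' @param path Dotted path.
#' @return The stored value.
#' @export
get_parameter <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- unclass(params)
  for (k in keys) {
    if (!k %in% names(out))
      stop("unknown parameter path '", path, "'", call. = FALSE)
    out <- out[[k]]
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parameter set into a path/value tibble
#'
#' @param x A `bcca_params` object.
#' @param ... Unused.
#' @return A tibble with columns `path` and `value` (values coerced to
#'   character for mixed types; numeric values keep full precision via
#'   `format`).
#' @export
tidy.bcca_params <- function(x, ...) {
  paths <- parameter_paths(x)
  tibble::tibble(
    path = paths,
    value = purrr::map_chr(paths, function(pp) {
      v <- get_parameter(x, pp)
      if (is.numeric(v)) format(v, digits = 15) else as.character(v)
    })
  )
}
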