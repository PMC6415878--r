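#' Round half away from zero
#'
#' Commercial rounding used throughout the population projection (R's
#' `round()` rounds half to even, which does not reproduce the published
#' yearly population sequence).
#' @param x numeric
#' @return `floor(x + 0.5)` for non-negative x.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Project the annual surveillance population
#'
#' Year-1 size grown by a constant annual rate. The exact (fractional)
#' geometric sequence `n1 * (1 + growth)^(t - 1)` is carried internally and
#' rounded half-up only for display: this is the convention that reproduces
#' the published year-by-year counts *and* their grand total and the
#' biopsy totals derived from it (sequential per-year integer rounding
#' drifts 1-5 off those).
#'
#' @param n1 Year-1 population (> 0).
#' @param growth Annual growth as a fraction (e.g. 0.20).
#' @param years Horizon length in years (>= 1).
#' @param exact If `TRUE`, return the unrounded sequence.
#' @return Numeric vector of length `years`; integer-valued unless
#'   `exact = TRUE`.
#' @examples
#' project_population(161657, 0.20, 7)
#' @export
project_population <- function(n1, growth, years, exact = FALSE) {
  if (years < 1) stop("years must be >= 1", call. = FALSE)
  if (n1 <= 0) stop("n1 must be > 0", call. = FALSE)
  if (growth < 0) stop("growth must be >= 0", call. = FALSE)
  pop <- n1 * (1 + growth)^(seq_len(years) - 1)
  if (exact) pop else round_half_up(pop)
}

#' Annual discount factors
#'
#' Costs after year 1 are discounted at a constant annual rate:
#' `factor[t] = (1 + rate)^-(t - 1)`, so year 1 is undiscounted.
#'
#' @param rate Annual discount rate as a fraction (>= 0); 0.035 by default
#'   in the model.
#' @param years Number of years.
#' @return Numeric vector of length `years`, starting at 1.
#' @export
discount_factors <- function(rate, years) {
  if (rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (years < 1) stop("years must be >= 1", call. = FALSE)
  (1 + rate)^-(seq_len(years) - 1)
}

#' Cohort trace: population and discounting over the horizon
#'
#' One row per model year with the projected population attending endoscopy,
#' the annual discount factor, and the running cumulative population. The
#' population column starts from the national year-1 cohort under the NHS
#' perspective and from the single-hospital cohort under the hospital
#' perspective.
#'
#' @param params A `bcca_params` object.
#' @param perspective `"NHS"` or `"hospital"`; defaults to the setting in
#'   `params$economics$perspective`.
#' @return A tibble with columns `year`, `population` (rounded for display),
#'   `population_exact` (the unrounded sequence every downstream computation
#'   uses), `discount_factor`, `cumulative_population`.
#' @examples
#' cohort_trace(default_parameters())
#' @export
cohort_trace <- function(params, perspective = params$economics$perspective) {
  stopifnot(inherits(params, "bcca_params"))
  n1 <- switch(perspective,
    NHS = params$epidemiology$n_year1,
    hospital = params$epidemiology$hospital_cohort,
    stop("unknown perspective '", perspective, "'", call. = FALSE)
  )
  years <- params$epidemiology$horizon_years
  g <- params$epidemiology$annual_growth
  pop_exact <- project_population(n1, g, years, exact = TRUE)
  tibble::tibble(
    year = seq_len(years),
    population = round_half_up(pop_exact),
    population_exact = pop_exact,
    discount_factor = discount_factors(params$economics$discount_rate, years),
    cumulative_population = cumsum(pop_exact)
  )
}

#' Total population over the horizon
#' @param trace A cohort trace from [cohort_trace()].
#' @param exact If `FALSE` (default), round the total to an integer.
#' @return Scalar sum of the yearly (exact) populations.
#' @export
cumulative_population <- function(trace, exact = FALSE) {
  s <- sum(trace$population_exact)
  if (exact) s else round_half_up(s)
}
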