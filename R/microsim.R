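#' Individual-patient microsimulation
#'
#' Monte-Carlo oracle for the cohort model: simulates i.i.d. patients with
#' exactly the cohort model's probabilistic structure. Each patient draws a
#' true disease state from the entry distribution, a technique (NBI or
#' HD-WLE by market share within the NBI arm), a test result from the
#' technique's sensitivity/specificity, an integer biopsy count whose mean
#' equals the technique's biopsies-per-procedure, Bernoulli adverse events,
#' and — when detected with high-grade dysplasia — treatment and an
#' eradication draw. In `long_term` mode each patient additionally walks the
#' 6-month transition matrix for 14 cycles with surveillance re-detection
#' mirroring [long_term_trace()]. Per-patient cost accrues under the
#' NHS tariff convention.
#'
#' Results are reproducible given `(n, seed)`.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer RNG seed.
#' @param params A `bcca_params` object.
#' @param arm `"nbi"` (mixed-technology arm) or `"wle"`.
#' @param mode `"diagnostic_only"` or `"long_term"`.
#' @param cycles Number of 6-month cycles in `long_term` mode.
#' @return A `bcca_microsim` tibble, one row per patient, with attributes
#'   `params`, `arm`, `mode`, `seed`.
#' @examples
#' sim <- simulate_patients(1000, seed = 1, default_parameters())
#' mean(sim$biopsies)
#' @export
simulate_patients <- function(n, seed, params = default_parameters(),
                              arm = c("nbi", "wle"),
                              mode = c("diagnostic_only", "long_term"),
                              cycles = 14) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  mix <- disease_mix(params$epidemiology$parasa)
  a <- params$accuracy
  pr <- params$procedure
  co <- params$costs
  share <- if (arm == "nbi") params$economics$market_share_nbi else 0

  state <- sample(bcca_states, n, replace = TRUE, prob = mix$fraction)
  technique <- ifelse(stats::rbinom(n, 1, share) == 1, "nbi", "wle")
  is_nbi <- technique == "nbi"

  if (params$economics$accuracy_level == "per_patient") {
    sens <- rep(a$per_patient_sens, n)
    spec <- rep(a$per_patient_spec, n)
  } else {
    sens <- ifelse(is_nbi, a$per_lesion_sens_nbi, a$per_lesion_sens_wle)
    spec <- ifelse(is_nbi, a$per_lesion_spec_nbi, a$per_lesion_spec_wle)
  }
  b_mean <- ifelse(is_nbi, pr$biopsies_nbi, pr$biopsies_wle)
  # integer biopsy count with the right mean: floor + Bernoulli(frac)
  biopsies <- floor(b_mean) + stats::rbinom(n, 1, b_mean - floor(b_mean))

  dysplastic <- state != "ND"
  positive <- logical(n)
  positive[dysplastic] <- stats::rbinom(sum(dysplastic), 1, sens[dysplastic]) == 1
  positive[!dysplastic] <- stats::rbinom(sum(!dysplastic), 1,
                                         1 - spec[!dysplastic]) == 1
  if (isTRUE(a$hist_layer_enabled)) {
    keep <- logical(n)
    tp <- positive & dysplastic
    fp <- positive & !dysplastic
    keep[tp] <- stats::rbinom(sum(tp), 1, a$hist_sens) == 1
    keep[fp] <- stats::rbinom(sum(fp), 1, 1 - a$hist_spec) == 1
    positive <- positive & keep
  }
  diagnosis <- ifelse(positive, ifelse(state == "ND", "LG", state), "ND")
  treated <- positive & state %in% c("HG", "EAC")
  erad_draw <- stats::rbinom(n, 1, pr$eradication_rate) == 1
  eradicated <- treated & state == "HG" & erad_draw

  # endoscopy adverse events under the configured exposure basis
  basis <- pr$ae_exposure_basis
  draw_endo_ae <- function(rate_nbi, rate_wle) {
    r <- ifelse(is_nbi, rate_nbi, rate_wle)
    switch(basis,
      per_procedure = stats::rbinom(n, 1, r),
      per_biopsy = stats::rbinom(n, biopsies, r),
      per_treated = ifelse(treated, stats::rbinom(n, 1, r), 0L),
      stop("unknown ae_exposure_basis '", basis, "'", call. = FALSE)
    )
  }
  ae_stricture <- draw_endo_ae(pr$endo_ae_nbi$stricture, pr$endo_ae_wle$stricture)
  ae_perforation <- draw_endo_ae(pr$endo_ae_nbi$perforation, pr$endo_ae_wle$perforation)
  ae_bleeding <- draw_endo_ae(pr$endo_ae_nbi$bleeding, pr$endo_ae_wle$bleeding)
  tae <- function(rate) ifelse(treated, stats::rbinom(n, 1, rate), 0L)
  tae_stricture <- tae(pr$treat_ae$stricture)
  tae_perforation <- tae(pr$treat_ae$perforation)
  tae_bleeding <- tae(pr$treat_ae$bleeding)

  ae_unit <- unlist(co$ae_costs)
  cost <- co$tariff_endoscopy + biopsies * co$cost_per_biopsy +
    (ae_stricture + tae_stricture) * ae_unit[["stricture"]] +
    (ae_bleeding + tae_bleeding) * ae_unit[["bleeding"]] +
    (ae_perforation + tae_perforation) * ae_unit[["perforation"]] +
    treated * co$tariff_emr_rfa

  out <- tibble::tibble(
    id = seq_len(n), true_state = state, technique, biopsies,
    diagnosis, positive, treated, eradicated,
    ae_stricture, ae_perforation, ae_bleeding,
    tae_stricture, tae_perforation, tae_bleeding,
    cost
  )

  if (mode == "long_term") {
    P <- default_transition_matrix()
    si <- match(state, bcca_states)
    # post-index state and surveillance interval (cycles between visits)
    si[eradicated] <- 1L
    interval <- ifelse(diagnosis == "ND", 6L, 1L)
    managed <- positive & state == "EAC"
    became_eac <- si == 4L
    n_surv_endo <- integer(n)
    n_surv_treat <- integer(n)
    managed_cycles <- integer(n)
    for (cyc in seq_len(cycles)) {
      act <- !managed
      # Markov step for everyone not under cancer management
      cur <- si[act]
      nxt <- cur
      for (s in 1:3) {
        idx <- which(cur == s)
        if (length(idx))
          nxt[idx] <- sample(1:4, length(idx), replace = TRUE, prob = P[s, ])
      }
      si[act] <- nxt
      new_eac <- si == 4L & !became_eac
      became_eac <- became_eac | new_eac
      # surveillance visit
      due <- (cyc %% interval == 0) & !managed
      n_surv_endo <- n_surv_endo + as.integer(due) + as.integer(managed)
      if (any(due)) {
        i_due <- which(due)
        st <- si[i_due]
        det <- stats::rbinom(length(i_due), 1, sens[i_due]) == 1
        # HG detected -> treatment
        hg_det <- i_due[st == 3L & det]
        if (length(hg_det)) {
          n_surv_treat[hg_det] <- n_surv_treat[hg_det] + 1L
          ok <- stats::rbinom(length(hg_det), 1, pr$eradication_rate) == 1
          si[hg_det[ok]] <- 1L
          interval[hg_det] <- 1L
        }
        # EAC detected -> cancer management
        eac_det <- i_due[st == 4L & det]
        managed[eac_det] <- TRUE
        # 36-month pool: LG detection and ND false positives step up to 6-monthly
        pool36 <- i_due[interval[i_due] == 6L]
        if (length(pool36)) {
          st36 <- si[pool36]
          lg_det <- pool36[st36 == 2L &
                           stats::rbinom(length(pool36), 1, sens[pool36]) == 1 &
                           st36 == 2L]
          fp <- pool36[st36 == 1L &
                       stats::rbinom(length(pool36), 1, 1 - spec[pool36]) == 1 &
                       st36 == 1L]
          interval[c(lg_det, fp)] <- 1L
        }
      }
      managed_cycles <- managed_cycles + as.integer(managed)
    }
    out$final_state <- bcca_states[si]
    out$became_eac <- became_eac
    out$n_surv_endo <- n_surv_endo
    out$n_surv_treat <- n_surv_treat
    out$managed_cycles <- managed_cycles
    out$cost <- out$cost +
      n_surv_endo * (co$tariff_endoscopy + b_mean * co$cost_per_biopsy) +
      n_surv_treat * co$tariff_emr_rfa +
      managed_cycles * co$cancer_cost_per_year / 2
  }

  class(out) <- c("bcca_microsim", class(out))
  attr(out, "params") <- params
  attr(out, "arm") <- arm
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  out
}

# save/restore the global RNG state so simulation is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Aggregate a microsimulation into per-patient statistics
#'
#' Sample means with standard errors for every statistic the cohort model
#' predicts as an expectation, optionally scaled to a cohort size.
#'
#' @param records A `bcca_microsim` tibble.
#' @param cohort_size Scale factor for the `scaled_total` column (default 1:
#'   per-patient means only).
#' @return A tibble with columns `statistic`, `mean`, `se`, `scaled_total`.
#' @export
aggregate_patients <- function(records, cohort_size = 1) {
  if (nrow(records) == 0) stop("empty record collection", call. = FALSE)
  n <- nrow(records)
  stat <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(n))
  cols <- list(
    biopsies = records$biopsies,
    detected_dysplastic = as.numeric(records$positive & records$true_state != "ND"),
    detected_hg = as.numeric(records$positive & records$true_state == "HG"),
    false_positive = as.numeric(records$positive & records$true_state == "ND"),
    correctly_identified = as.numeric(
      (records$positive & records$true_state != "ND") |
      (!records$positive & records$true_state == "ND")),
    treated = as.numeric(records$treated),
    eradicated = as.numeric(records$eradicated),
    strictures = records$ae_stricture + records$tae_stricture,
    bleedings = records$ae_bleeding + records$tae_bleeding,
    perforations = records$ae_perforation + records$tae_perforation,
    cost = records$cost
  )
  if (attr(records, "mode") == "long_term") {
    cols$incident_eac <- as.numeric(records$became_eac & records$true_state != "EAC")
    cols$surveillance_endoscopies <- records$n_surv_endo
  }
  purrr::imap_dfr(cols, function(x, nm) {
    s <- stat(x)
    tibble::tibble(statistic = nm, mean = s[["mean"]], se = s[["se"]],
                   scaled_total = s[["mean"]] * cohort_size)
  })
}

#' Cohort-model expectations per patient
#'
#' The deterministic counterparts of [aggregate_patients()]'s statistics,
#' computed for a cohort of size 1 — what the microsimulation means should
#' converge to.
#'
#' @param params A `bcca_params` object.
#' @param arm `"nbi"` or `"wle"`.
#' @return A tibble with columns `statistic`, `expected`.
#' @export
cohort_expectations <- function(params = default_parameters(),
                                arm = c("nbi", "wle")) {
  arm <- match.arg(arm)
  inp <- arm_inputs(params, arm)
  mix <- disease_mix(params$epidemiology$parasa)
  hist <- if (isTRUE(params$accuracy$hist_layer_enabled)) {
    list(sens = params$accuracy$hist_sens, spec = params$accuracy$hist_spec)
  } else NULL
  cls <- classify_patients(1, mix, inp$sens, inp$spec, hist)
  tc <- treatment_counts(cls, params$procedure$eradication_rate)
  ae <- adverse_events(params, arm, cohort = 1, treated = tc$treated,
                       biopsies = inp$biopsies)
  ae_tot <- ae |>
    dplyr::group_by(event) |>
    dplyr::summarise(count = sum(count), .groups = "drop")
  co <- params$costs
  ae_unit <- unlist(co$ae_costs)
  exp_cost <- co$tariff_endoscopy + inp$biopsies * co$cost_per_biopsy +
    sum(ae_tot$count * ae_unit[ae_tot$event]) +
    tc$treated * co$tariff_emr_rfa
  tibble::tibble(
    statistic = c("biopsies", "detected_dysplastic", "detected_hg",
                  "false_positive", "correctly_identified", "treated",
                  "eradicated", "strictures", "bleedings", "perforations",
                  "cost"),
    expected = c(
      inp$biopsies,
      sum(cls_get(cls, c("LG", "HG", "EAC"), "positive")),
      cls_get(cls, "HG", "positive"),
      cls_get(cls, "ND", "positive"),
      correctly_identified(cls),
      tc$treated,
      tc$strict_successes,
      ae_tot$count[match("stricture", ae_tot$event)],
      ae_tot$count[match("bleeding", ae_tot$event)],
      ae_tot$count[match("perforation", ae_tot$event)],
      exp_cost
    )
  )
}

#' Validate cohort-model expectations against the microsimulation
#'
#' Flags every statistic whose cohort expectation falls outside the
#' microsimulation mean +/- `tolerance_se` standard errors. Zero-variance
#' statistics require exact equality.
#'
#' @param records A `bcca_microsim` tibble (or its [aggregate_patients()]
#'   output via `agg`).
#' @param expectations Tibble from [cohort_expectations()]; must come from
#'   the same parameterization.
#' @param tolerance_se Width of the acceptance band in standard errors.
#' @return A tibble `statistic`, `microsim`, `se`, `expected`, `z`, `pass`.
#' @export
validate_against_cohort <- function(records,
                                    expectations = cohort_expectations(
                                      attr(records, "params"),
                                      attr(records, "arm")),
                                    tolerance_se = 3) {
  agg <- aggregate_patients(records)
  out <- dplyr::inner_join(agg, expectations, by = "statistic") |>
    dplyr::mutate(
      z = ifelse(se > 0, (mean - expected) / se, ifelse(mean == expected, 0, Inf)),
      pass = abs(z) <= tolerance_se
    ) |>
    dplyr::select(statistic, microsim = mean, se, expected, z, pass)
  out
}

#' Export patient records to CSV
#' @param records A `bcca_microsim` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
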