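#' Markov/decision-tree state labels
#' @keywords internal
bcca_states <- c("ND", "LG", "HG", "EAC")

#' Disease-state mix of the entering cohort
#'
#' Converts the source-cohort integer counts (a longitudinal Barrett's cohort
#' of 2,696 patients) into the entry-node state distribution of the decision
#' tree. The exact fractions are used, not the rounded percentages: 106/2696
#' for HG, for example, is what downstream event counts depend on.
#'
#' @param parasa Named list of counts `total`, `dysplastic`, `lg`, `hg`,
#'   `eac` (defaults taken from [default_parameters()]).
#' @return A tibble with columns `state` (`ND`, `LG`, `HG`, `EAC`) and
#'   `fraction`, summing to 1.
#' @examples
#' disease_mix()
#' @export
disease_mix <- function(parasa = default_parameters()$epidemiology$parasa) {
  if (parasa$dysplastic > parasa$total)
    stop("dysplastic count exceeds total", call. = FALSE)
  if (parasa$lg + parasa$hg + parasa$eac != parasa$dysplastic)
    stop("lg + hg + eac must equal dysplastic", call. = FALSE)
  tibble::tibble(
    state = bcca_states,
    fraction = c(parasa$total - parasa$dysplastic,
                 parasa$lg, parasa$hg, parasa$eac) / parasa$total
  )
}

#' Market-share blend of a per-technique quantity
#'
#' The "NBI" strategy is a mixed-technology arm: a `share` fraction of
#' procedures use NBI targeted biopsies, the remainder stay on HD-WLE with
#' the Seattle protocol. Any per-procedure quantity (biopsies, adverse-event
#' rates, staff cost) blends linearly.
#'
#' @param share NBI market share in \[0, 1\].
#' @param x_nbi,x_wle The technique-specific values.
#' @return `share * x_nbi + (1 - share) * x_wle`.
#' @examples
#' blended_biopsies(0.84, 3.6, 7.6) # 4.24 biopsies/procedure in the NBI arm
#' @export
blended_biopsies <- function(share, x_nbi, x_wle) {
  if (share < 0 || share > 1) stop("share must be in [0,1]", call. = FALSE)
  share * x_nbi + (1 - share) * x_wle
}

# Arm-level effective inputs. arm is "nbi" (mixed, share = market_share_nbi)
# or "wle" (pure HD-WLE). Returns sens/spec at the configured accuracy level,
# biopsies per procedure, and endoscopy AE rates, all market-share blended
# for the NBI arm.
arm_inputs <- function(params, arm = c("nbi", "wle")) {
  arm <- match.arg(arm)
  share <- if (arm == "nbi") params$economics$market_share_nbi else 0
  a <- params$accuracy
  if (params$economics$accuracy_level == "per_patient") {
    sens <- a$per_patient_sens
    spec <- a$per_patient_spec
  } else {
    sens <- blended_biopsies(share, a$per_lesion_sens_nbi, a$per_lesion_sens_wle)
    spec <- blended_biopsies(share, a$per_lesion_spec_nbi, a$per_lesion_spec_wle)
  }
  pr <- params$procedure
  ae <- purrr::map2(pr$endo_ae_nbi, pr$endo_ae_wle,
                    function(n, w) blended_biopsies(share, n, w))
  list(
    arm = arm,
    share = share,
    sens = sens,
    spec = spec,
    biopsies = blended_biopsies(share, pr$biopsies_nbi, pr$biopsies_wle),
    endo_ae = ae
  )
}

#' Classify a cohort through the diagnostic decision tree
#'
#' Applies the endoscopic test to a cohort distributed over the four disease
#' states. Dysplastic patients (LG, HG, EAC) test positive with probability
#' `sens` and are missed with `1 - sens`; grade assignment among detected
#' dysplastics is taken as correct (accuracy is binary). Non-dysplastic
#' patients test negative with probability `spec`; false positives are
#' labelled LG (they enter 6-monthly surveillance in long-term scenarios but
#' are never resected). Expected (fractional) counts are carried; rounding
#' happens only at report time.
#'
#' An optional histopathology confirmation layer (sensitivity
#' `hist_sens`, specificity `hist_spec`) can be applied to all endoscopy
#' positives; it is off in the base case.
#'
#' @param cohort Cohort size (>= 0).
#' @param mix State distribution tibble from [disease_mix()].
#' @param sens,spec Test operating characteristics in \[0, 1\].
#' @param hist Either `NULL` (no confirmation layer) or a list with
#'   `sens` and `spec`.
#' @return A `bcca_classification` tibble with columns `state`, `n` (true
#'   count), `positive` (labelled dysplastic: true positives by grade, false
#'   positives for the ND row) and `negative` (missed dysplastics by grade,
#'   true negatives for the ND row). `positive + negative == n` per row.
#' @examples
#' classify_patients(2087946, disease_mix(), sens = 0.942, spec = 0.944)
#' @export
classify_patients <- function(cohort, mix, sens, spec, hist = NULL) {
  if (cohort < 0) stop("cohort must be >= 0", call. = FALSE)
  stopifnot(all(mix$state == bcca_states))
  n <- cohort * mix$fraction
  pos <- c(n[1] * (1 - spec), n[2] * sens, n[3] * sens, n[4] * sens)
  if (!is.null(hist)) {
    # positives are sent to histology; dysplastic positives confirmed with
    # hist sensitivity, ND false positives confirmed with 1 - hist specificity
    pos <- pos * c(1 - hist$spec, hist$sens, hist$sens, hist$sens)
  }
  out <- tibble::tibble(state = bcca_states, n = n,
                        positive = pos, negative = n - pos)
  class(out) <- c("bcca_classification", class(out))
  attr(out, "sens") <- sens
  attr(out, "spec") <- spec
  out
}

# Convenience accessors for a classification tibble
cls_get <- function(cls, state, col) cls[[col]][match(state, cls$state)]

#' Correctly identified cases
#'
#' True positives (detected dysplastics of any grade) plus true negatives.
#' @param cls A `bcca_classification`.
#' @return Expected count.
#' @export
correctly_identified <- function(cls) {
  sum(cls_get(cls, c("LG", "HG", "EAC"), "positive")) + cls_get(cls, "ND", "negative")
}

#' Treatment counts downstream of the decision tree
#'
#' Detected HG patients receive endomucosal resection + radiofrequency
#' ablation; detected EAC patients receive cancer treatment billed at the
#' same tariff. Two eradication conventions are returned: the *reported*
#' successful-eradication count is the detected-HG count (the convention the
#' published outcome rows follow), while `strict_successes` applies the
#' eradication rate and is what the progression module uses to return
#' patients to the non-dysplastic surveillance pool.
#'
#' @param cls A `bcca_classification`.
#' @param eradication_rate Probability of successful dysplasia eradication.
#' @return A list with `treated`, `reported_eradications`,
#'   `strict_successes`.
#' @export
treatment_counts <- function(cls, eradication_rate) {
  det_hg <- cls_get(cls, "HG", "positive")
  det_eac <- cls_get(cls, "EAC", "positive")
  list(
    treated = det_hg + det_eac,
    reported_eradications = det_hg,
    strict_successes = det_hg * eradication_rate
  )
}

#' Expected adverse-event counts for one arm
#'
#' Endoscopy-related events (strictures, perforations, bleedings) scale with
#' an exposure that depends on the accounting basis: number of procedures
#' (default), total biopsies, or treated patients. The NBI arm's endoscopy
#' rates are market-share blends of the two techniques' rates, so the AE
#' burden falls linearly with the biopsy reduction. Treatment-related events
#' scale with the number of treated patients in both arms.
#'
#' @param params A `bcca_params` object.
#' @param arm `"nbi"` or `"wle"`.
#' @param cohort Number of index procedures.
#' @param treated Number of treated patients.
#' @param biopsies Total biopsies taken (used for the `per_biopsy` basis).
#' @param basis Exposure basis; defaults to the parameter setting.
#' @return A tibble with columns `source` (`endoscopy` / `treatment`),
#'   `event`, `count`.
#' @export
adverse_events <- function(params, arm, cohort, treated, biopsies = NULL,
                           basis = params$procedure$ae_exposure_basis) {
  inp <- arm_inputs(params, arm)
  exposure <- switch(basis,
    per_procedure = cohort,
    per_biopsy = {
      if (is.null(biopsies)) biopsies <- cohort * inp$biopsies
      biopsies
    },
    per_treated = treated,
    stop("unknown ae_exposure_basis '", basis, "'", call. = FALSE)
  )
  endo <- tibble::tibble(
    source = "endoscopy",
    event = names(inp$endo_ae),
    count = unname(unlist(inp$endo_ae)) * exposure
  )
  tr <- params$procedure$treat_ae
  treat <- tibble::tibble(
    source = "treatment",
    event = names(tr),
    count = unname(unlist(tr)) * treated
  )
  dplyr::bind_rows(endo, treat)
}
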