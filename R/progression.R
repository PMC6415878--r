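#' Six-month disease progression matrix
#'
#' The default transition probabilities per 6-month cycle over the states
#' ND -> LG -> HG -> EAC, elaborated from a sham-controlled ablation trial.
#' There are no backward transitions (no regression) and adenocarcinoma is
#' absorbing.
#'
#' @return A 4x4 row-stochastic matrix with dimnames
#'   `c("ND","LG","HG","EAC")`.
#' @examples
#' default_transition_matrix()
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    0.9500, 0.0500, 0.0000, 0.0000,
    0.0000, 0.9318, 0.0682, 0.0000,
    0.0000, 0.0000, 0.9048, 0.0952,
    0.0000, 0.0000, 0.0000, 1.0000
  ), nrow = 4, byrow = TRUE, dimnames = list(bcca_states, bcca_states))
  m
}

#' Evolve a state distribution through the Markov model
#'
#' Applies the 6-month transition matrix `cycles` times. Probability (or
#' population) mass is conserved.
#'
#' @param dist Either a tibble with columns `state`/`fraction` (as returned
#'   by [disease_mix()]) or a numeric vector of length 4 in state order
#'   ND, LG, HG, EAC.
#' @param matrix Transition matrix; defaults to
#'   [default_transition_matrix()].
#' @param cycles Non-negative integer number of 6-month cycles.
#' @return Same shape as `dist`.
#' @examples
#' evolve_states(c(ND = 1, LG = 0, HG = 0, EAC = 0), cycles = 2)
#' @export
evolve_states <- function(dist, matrix = default_transition_matrix(), cycles = 1) {
  if (cycles < 0) stop("cycles must be >= 0", call. = FALSE)
  tib <- is.data.frame(dist)
  v <- if (tib) dist$fraction else as.numeric(dist)
  stopifnot(length(v) == 4)
  for (i in seq_len(cycles)) v <- as.numeric(v %*% matrix)
  if (tib) {
    dist$fraction <- v
    dist
  } else {
    stats::setNames(v, bcca_states)
  }
}

#' Surveillance plan
#'
#' Surveillance endoscopy intervals by diagnosed state, in months: patients
#' believed non-dysplastic return every 36 months; diagnosed LG and
#' post-treatment patients (HG, EAC) return every 6 months. Intervals must be
#' positive multiples of the 6-month cycle.
#'
#' @param nd,lg,hg_post,eac_post Intervals in months.
#' @return Named list of intervals in cycles.
#' @export
surveillance_plan <- function(nd = 36, lg = 6, hg_post = 6, eac_post = 6) {
  iv <- c(nd = nd, lg = lg, hg_post = hg_post, eac_post = eac_post)
  if (any(iv <= 0) || any(iv %% 6 != 0))
    stop("surveillance intervals must be positive multiples of 6 months",
         call. = FALSE)
  as.list(iv / 6)
}

#' Long-term follow-up of a classified cohort
#'
#' Walks a cohort, already classified by the index endoscopy, through the
#' 6-month-cycle Markov model under surveillance. Bookkeeping:
#'
#' * true negatives and *missed* dysplastics (false negatives) sit in the
#'   36-month surveillance pool, progress under the transition matrix, and
#'   are re-tested with the arm's sensitivity/specificity at each attended
#'   visit (no detection between visits);
#' * diagnosed LG, false-positive ND (labelled LG) and post-treatment
#'   patients sit in the 6-month pool; at each visit HG and EAC present in
#'   the pool are detected with the arm's sensitivity, HG detections are
#'   treated (successes return to the non-dysplastic state, failures remain
#'   HG), EAC detections move under cancer management;
#' * diagnosed EAC patients accrue cancer-management cost while under
#'   management and attend 6-monthly surveillance.
#'
#' Incident EAC counts every first entry into the adenocarcinoma state,
#' detected or not.
#'
#' @param cls A `bcca_classification` for the entering cohort.
#' @param params A `bcca_params` object.
#' @param arm `"nbi"` or `"wle"` (controls re-test accuracy).
#' @param cycles Number of 6-month cycles to run (14 for the 7-year horizon).
#' @param plan A [surveillance_plan()].
#' @param matrix Transition matrix; [default_transition_matrix()] unless
#'   overridden.
#' @return A `bcca_longterm` list with `per_cycle` (tibble: `cycle`,
#'   `endoscopies`, `treatments`, `incident_eac`, `managed_eac`, state
#'   occupancy columns) and totals `incident_eac`, `endoscopies`,
#'   `treatments`.
#' @export
long_term_trace <- function(cls, params, arm = "nbi", cycles = 14,
                            plan = surveillance_plan(),
                            matrix = default_transition_matrix()) {
  if (cycles < 0) stop("cycles must be >= 0", call. = FALSE)
  if (plan$lg != plan$hg_post || plan$lg != plan$eac_post)
    stop("inconsistent plan: post-diagnosis intervals must coincide (6-month pool)",
         call. = FALSE)
  inp <- arm_inputs(params, arm)
  P <- matrix
  erad <- params$procedure$eradication_rate

  det <- function(s) cls_get(cls, s, "positive")
  mis <- function(s) cls_get(cls, s, "negative")
  # pools: 4-state mass vectors
  surv36 <- c(mis("ND"), mis("LG"), mis("HG"), mis("EAC"))
  surv6 <- c(det("ND"),                        # false positives, true ND
             det("LG"),
             det("HG") * (1 - erad),           # treatment failures
             0)
  surv6[1] <- surv6[1] + 0                     # (successes added below)
  surv6[1] <- surv6[1] + det("HG") * erad      # eradicated, back to ND state
  managed_eac <- det("EAC")

  rows <- vector("list", cycles)
  tot_endo <- 0
  tot_treat <- 0
  tot_inc <- 0
  for (cyc in seq_len(cycles)) {
    inc <- 0
    step <- function(v) as.numeric(v %*% P)
    new36 <- step(surv36); inc <- inc + (new36[4] - surv36[4])
    new6 <- step(surv6);   inc <- inc + (new6[4] - surv6[4])
    surv36 <- new36
    surv6 <- new6
    endo <- 0
    treat <- 0
    visit <- function(v) {
      endo <<- endo + sum(v)
      # HG detected -> treatment; EAC detected -> cancer management
      det_hg <- v[3] * inp$sens
      det_eac <- v[4] * inp$sens
      treat <<- treat + det_hg
      managed_eac <<- managed_eac + det_eac
      v[3] <- v[3] - det_hg
      v[4] <- v[4] - det_eac
      list(v = v, det_hg = det_hg)
    }
    if (cyc %% plan$lg == 0) {
      res <- visit(surv6)
      surv6 <- res$v
      # successes return to ND within the 6-month pool; failures stay HG
      surv6[1] <- surv6[1] + res$det_hg * erad
      surv6[3] <- surv6[3] + res$det_hg * (1 - erad)
      endo <- endo + managed_eac   # post-treatment EAC surveillance visit
    }
    if (cyc %% plan$nd == 0) {
      res <- visit(surv36)
      v <- res$v
      # newly detected LG and false positives move to 6-month surveillance
      det_lg <- v[2] * inp$sens
      fp_nd <- v[1] * (1 - inp$spec)
      v[2] <- v[2] - det_lg
      v[1] <- v[1] - fp_nd
      surv6[2] <- surv6[2] + det_lg
      surv6[1] <- surv6[1] + fp_nd
      surv6[1] <- surv6[1] + res$det_hg * erad
      surv6[3] <- surv6[3] + res$det_hg * (1 - erad)
      surv36 <- v
    }
    tot_endo <- tot_endo + endo
    tot_treat <- tot_treat + treat
    tot_inc <- tot_inc + inc
    occ <- surv36 + surv6 + c(0, 0, 0, managed_eac)
    rows[[cyc]] <- tibble::tibble(
      cycle = cyc, endoscopies = endo, treatments = treat,
      incident_eac = inc, managed_eac = managed_eac,
      nd = occ[1], lg = occ[2], hg = occ[3], eac = occ[4]
    )
  }
  per_cycle <- dplyr::bind_rows(rows)
  structure(
    list(per_cycle = per_cycle,
         incident_eac = tot_inc,
         endoscopies = tot_endo,
         treatments = tot_treat,
         entry_mass = sum(cls$n)),
    class = "bcca_longterm"
  )
}
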