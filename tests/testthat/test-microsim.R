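test_that("simulation is deterministic given (n, seed) and seeds differ", {
  p <- default_parameters()
  a <- simulate_patients(2000, seed = 11, p)
  b <- simulate_patients(2000, seed = 11, p)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_patients(2000, seed = 12, p)
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
  # different seeds are statistically compatible: biopsy means within 5 SE
  expect_lt(abs(mean(a$biopsies) - mean(c$biopsies)),
            5 * stats::sd(a$biopsies) / sqrt(2000))
  expect_error(simulate_patients(0, 1, p), "n must be")
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_patients(100, seed = 5, default_parameters()))
  expect_identical(.Random.seed, before)
})

test_that("degenerate probabilities give zero-variance outputs", {
  p <- default_parameters()
  p <- apply_override(p, "accuracy.per_patient_sens", 1)
  p <- apply_override(p, "accuracy.per_patient_spec", 1)
  p <- apply_override(p, "procedure.eradication_rate", 1)
  p <- apply_override(p, "procedure.biopsies_nbi", 4)    # integer counts
  p <- apply_override(p, "procedure.biopsies_wle", 4)
  for (ev in c("stricture", "perforation", "bleeding")) {
    p <- apply_override(p, paste0("procedure.endo_ae_nbi.", ev), 0)
    p <- apply_override(p, paste0("procedure.endo_ae_wle.", ev), 0)
    p <- apply_override(p, paste0("procedure.treat_ae.", ev), 1)
  }
  sim <- simulate_patients(500, seed = 3, p)
  expect_true(all(sim$positive == (sim$true_state != "ND")))
  expect_equal(stats::sd(sim$biopsies), 0)
  agg <- aggregate_patients(sim)
  expect_equal(agg$se[agg$statistic == "biopsies"], 0)
  # zero-variance statistics validate exactly
  v <- validate_against_cohort(sim)
  expect_true(v$pass[v$statistic == "biopsies"])
})

test_that("microsim means agree with cohort expectations within 3 SE", {
  p <- default_parameters()
  for (arm in c("nbi", "wle")) {
    sim <- simulate_patients(4e4, seed = 17, p, arm = arm)
    v <- validate_against_cohort(sim)
    expect_true(all(v$pass), info = paste("arm", arm, ":",
      paste(v$statistic[!v$pass], collapse = ", ")))
  }
})

test_that("validation flags a corrupted cohort expectation", {
  sim <- simulate_patients(2e4, seed = 21, default_parameters())
  exp_ok <- cohort_expectations(default_parameters(), "nbi")
  exp_bad <- dplyr::mutate(exp_ok, expected = expected * 1.5)
  v <- validate_against_cohort(sim, exp_bad)
  expect_false(all(v$pass))
})

test_that("estimates converge to the cohort expectation as n grows", {
  p <- default_parameters()
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    sim <- simulate_patients(n, seed = 31, p)
    abs(mean(sim$biopsies) - 4.24)
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("long-term microsim matches the cohort Markov bookkeeping", {
  p <- default_parameters()
  n <- 3e4
  sim <- simulate_patients(n, seed = 41, p, arm = "nbi", mode = "long_term")
  agg <- aggregate_patients(sim)
  cls <- classify_patients(1, disease_mix(), 0.942, 0.944)
  lt <- long_term_trace(cls, p, "nbi", cycles = 14)
  get <- function(s) agg[agg$statistic == s, ]
  inc <- get("incident_eac")
  expect_lt(abs(inc$mean - lt$incident_eac), 3 * inc$se)
  endo <- get("surveillance_endoscopies")
  expect_lt(abs(endo$mean - lt$endoscopies), 3 * endo$se)
  # pure-LG start, detection switched off so treatment cannot interfere:
  # the 6-month HG inflow fraction is the printed per-cycle hazard 0.0682
  p_lg <- load_parameters(overrides = list(
    epidemiology = list(parasa = list(total = 1000L, dysplastic = 1000L,
                                      lg = 1000L, hg = 0L, eac = 0L)),
    accuracy = list(per_patient_sens = 0)))
  one <- simulate_patients(n, seed = 47, p_lg, mode = "long_term", cycles = 1)
  expect_true(all(one$true_state == "LG"))
  se1 <- sqrt(0.0682 * (1 - 0.0682) / n)
  expect_lt(abs(mean(one$final_state == "HG") - 0.0682), 3 * se1)
})

test_that("aggregate scales to the cohort and rejects empty input", {
  sim <- simulate_patients(1000, seed = 51, default_parameters())
  agg <- aggregate_patients(sim, cohort_size = 2087946)
  bio <- agg[agg$statistic == "biopsies", ]
  expect_equal(bio$scaled_total, bio$mean * 2087946)
  expect_error(aggregate_patients(sim[0, ]), "empty")
})
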