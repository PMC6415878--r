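test_that("disease mix reproduces the entry-node distribution", {
  mix <- disease_mix()
  expect_equal(mix$fraction[mix$state == "ND"], 1791 / 2696)
  expect_equal(round(mix$fraction[mix$state == "ND"], 3), 0.664)
  # LG share *of dysplastic* patients is 83.0%
  expect_equal(round(751 / 905, 3), 0.830)
  expect_equal(sum(mix$fraction), 1, tolerance = 1e-12)
  expect_error(disease_mix(list(total = 100, dysplastic = 150, lg = 100,
                                hg = 30, eac = 20)), "exceeds")
})

test_that("biopsies per procedure blend linearly with market share", {
  expect_equal(blended_biopsies(1.0, 3.6, 7.6), 3.6)
  expect_equal(blended_biopsies(0.0, 3.6, 7.6), 7.6)
  expect_equal(blended_biopsies(0.84, 3.6, 7.6), 4.24)
  expect_error(blended_biopsies(1.2, 3.6, 7.6), "share")
})

test_that("classification conserves patients and matches expected counts", {
  mix <- disease_mix()
  cohort <- 2087946.2890625  # exact 7-year cumulative population
  cls <- classify_patients(cohort, mix, sens = 0.942, spec = 0.944)
  expect_equal(sum(cls$positive + cls$negative), cohort, tolerance = 1e-9)
  expect_equal(cls$positive[cls$state == "HG"],
               cohort * 106 / 2696 * 0.942, tolerance = 1e-9)
  expect_equal(cls$positive[cls$state == "HG"], 77332, tolerance = 1)
  expect_equal(cls$positive[cls$state == "ND"],
               cohort * 1791 / 2696 * 0.056, tolerance = 1e-9)
  expect_equal(cls$positive[cls$state == "ND"], 77672, tolerance = 1)
})

test_that("a perfect test has no misses and no false positives", {
  cls <- classify_patients(1e5, disease_mix(), sens = 1, spec = 1)
  expect_equal(cls$negative[cls$state != "ND"], rep(0, 3))
  expect_equal(cls$positive[cls$state == "ND"], 0)
  expect_error(classify_patients(-1, disease_mix(), 0.9, 0.9), "cohort")
})

test_that("classification is monotone in accuracy and linear in cohort size", {
  mix <- disease_mix()
  sens_grid <- seq(0.5, 1, by = 0.1)
  det <- vapply(sens_grid, function(s) {
    cls <- classify_patients(1000, mix, s, 0.944)
    sum(cls$positive[cls$state != "ND"])
  }, numeric(1))
  expect_true(all(diff(det) > 0))
  fp <- vapply(sens_grid, function(s) {
    cls <- classify_patients(1000, mix, 0.942, s)
    cls$positive[cls$state == "ND"]
  }, numeric(1))
  expect_true(all(diff(fp) < 0))
  c1 <- classify_patients(1000, mix, 0.942, 0.944)
  c5 <- classify_patients(5000, mix, 0.942, 0.944)
  expect_equal(c5$positive, 5 * c1$positive, tolerance = 1e-12)
})

test_that("histology confirmation layer prunes false positives", {
  mix <- disease_mix()
  plain <- classify_patients(1000, mix, 0.942, 0.944)
  conf <- classify_patients(1000, mix, 0.942, 0.944,
                            hist = list(sens = 1.0, spec = 0.629))
  expect_equal(conf$positive[conf$state == "ND"],
               plain$positive[plain$state == "ND"] * (1 - 0.629),
               tolerance = 1e-12)
  # perfect histology sensitivity: no extra missed dysplastics
  expect_equal(conf$positive[conf$state != "ND"],
               plain$positive[plain$state != "ND"], tolerance = 1e-12)
})

test_that("treatment counts follow the detected-HG conventions", {
  cls <- classify_patients(2087946.2890625, disease_mix(), 0.942, 0.944)
  tc <- treatment_counts(cls, 0.949)
  expect_equal(tc$reported_eradications, 77331, tolerance = 1)
  expect_equal(tc$strict_successes, 77331.46 * 0.949, tolerance = 1)
  expect_equal(tc$treated,
               cls$positive[cls$state == "HG"] + cls$positive[cls$state == "EAC"])
  z <- treatment_counts(classify_patients(1000, disease_mix(), 0, 0.944), 0.949)
  expect_equal(z$treated, 0)
})

test_that("adverse events blend rates, respect the exposure basis, and scale", {
  p <- default_parameters()
  # blended NBI-arm perforation rate
  expect_equal(blended_biopsies(0.84, 0.014, 0.030), 0.01656)
  ae <- adverse_events(p, "nbi", cohort = 1000, treated = 0)
  perf <- ae$count[ae$event == "perforation" & ae$source == "endoscopy"]
  expect_equal(perf, 1000 * 0.01656, tolerance = 1e-9)
  ae_w <- adverse_events(p, "wle", cohort = 1000, treated = 0)
  expect_equal(ae_w$count[ae_w$event == "perforation" & ae_w$source == "endoscopy"], 30)
  # treatment AEs scale with treated patients in both arms
  ae_t <- adverse_events(p, "wle", cohort = 0, treated = 200)
  expect_equal(ae_t$count[ae_t$event == "stricture" & ae_t$source == "treatment"],
               200 * 0.335)
  # per-biopsy basis multiplies by the biopsy count instead
  ae_b <- adverse_events(p, "wle", cohort = 1000, treated = 0,
                         basis = "per_biopsy")
  expect_equal(ae_b$count[ae_b$event == "perforation" & ae_b$source == "endoscopy"],
               1000 * 7.6 * 0.030, tolerance = 1e-9)
  expect_error(adverse_events(p, "wle", 10, 0, basis = "per_lesion"), "basis")
  # zero rates give an all-zero profile
  p0 <- p
  for (ev in c("stricture", "perforation", "bleeding")) {
    p0 <- apply_override(p0, paste0("procedure.endo_ae_nbi.", ev), 0)
    p0 <- apply_override(p0, paste0("procedure.endo_ae_wle.", ev), 0)
    p0 <- apply_override(p0, paste0("procedure.treat_ae.", ev), 0)
  }
  expect_equal(sum(adverse_events(p0, "nbi", 1000, 100)$count), 0)
})

test_that("NBI-arm per-patient endoscopy AE burden never exceeds HD-WLE's", {
  p <- default_parameters()
  for (share in c(0, 0.25, 0.5, 0.84, 1)) {
    ps <- apply_override(p, "economics.market_share_nbi", share)
    a_n <- adverse_events(ps, "nbi", 1000, 0)
    a_w <- adverse_events(ps, "wle", 1000, 0)
    expect_lte(sum(a_n$count), sum(a_w$count))
  }
})
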