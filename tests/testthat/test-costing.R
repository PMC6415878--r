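test_that("per-patient histology costs reproduce the derived unit costs", {
  expect_equal(7.6 * 82, 623.2)
  expect_equal(3.6 * 82, 295.2)
  # the mixed NBI arm: 4.24 biopsies x GBP 82 per exam
  expect_equal(blended_biopsies(0.84, 3.6, 7.6) * 82, 347.68)
  expect_equal(histopathology_cost(c(1), 623.2, c(1)), 623.2)
  expect_equal(histopathology_cost(numeric(0), 82, numeric(0)), 0)
})

test_that("staff micro-costs per endoscopy match the rate x time sums", {
  p <- default_parameters()
  expect_equal(staff_cost_per_procedure(p, "wle"),
               0.30 * 23 + 0.89 * 41 + 0.50 * 142 + 0.30 * 100 + 0.30 * 142)
  expect_equal(staff_cost_per_procedure(p, "wle"), 186.99)
  expect_equal(staff_cost_per_procedure(p, "nbi"), 167.72)
  # nurse non-contact time scales with the biopsy count (0.89 x 3.6/7.6 = 0.42)
  expect_equal(round(0.89 * 3.6 / 7.6, 2), 0.42)
  p0 <- p
  for (role in names(p$costs$staff_times_nbi))
    p0 <- apply_override(p0, paste0("costs.staff_times_nbi.", role), 0)
  expect_equal(staff_cost_per_procedure(p0, "nbi"), 0)
})

test_that("adverse-event costs price each event at its unit cost", {
  costs <- default_parameters()$costs$ae_costs
  one_perf <- tibble::tibble(year = 1L, event = "perforation", count = 1)
  expect_equal(ae_cost_total(one_perf, costs, 1), 2852)
  two <- tibble::tibble(year = c(1L, 1L), event = c("stricture", "bleeding"),
                        count = c(1, 1))
  expect_equal(ae_cost_total(two, costs, 1), 784)
  expect_equal(ae_cost_total(two[0, ], costs, 1), 0)
  # discounting applies by year
  expect_equal(ae_cost_total(dplyr::mutate(one_perf, year = 2L), costs,
                             discount_factors(0.035, 2)),
               2852 / 1.035)
})

test_that("capital upgrade quantities follow the estate shares", {
  p <- default_parameters()
  eq <- p$equipment
  systems_units <- eq$hospitals * eq$olympus_share * (1 - eq$nbi_capable_share) *
    eq$rooms_per_hospital
  expect_equal(systems_units, 115.5609, tolerance = 1e-4)
  training <- eq$hospitals * eq$olympus_share * eq$endoscopists_per_hospital *
    eq$trained_share * eq$training_days_nbi * eq$training_cost_per_day_nbi
  expect_equal(training, 772218, tolerance = 1)
  # fully equipped estate: nothing to buy, nobody to train
  p_full <- p
  p_full <- apply_override(p_full, "equipment.nbi_capable_share", 1)
  p_full <- apply_override(p_full, "equipment.hd_scope_share", 1)
  p_full <- apply_override(p_full, "equipment.trained_share", 0)
  p_full <- apply_override(p_full, "equipment.replacement_rate", 0)
  cap <- capital_equipment_cost(p_full, "nbi", "NHS")
  expect_equal(sum(cap$cost), 0)
})

test_that("capital charges amortize evenly and discount like other costs", {
  p <- default_parameters()
  f <- discount_factors(0.035, 7)
  cap <- capital_equipment_cost(p, "nbi", "NHS", f)
  undisc <- cap$cost / f
  expect_equal(diff(undisc) / undisc[1], rep(0, 6), tolerance = 1e-9)
  # the NBI arm invests more in equipment than the HD-WLE arm
  cap_w <- capital_equipment_cost(p, "wle", "NHS", f)
  expect_gt(sum(cap$cost), sum(cap_w$cost))
})

test_that("cost categories are linear in their unit costs", {
  p <- default_parameters()
  base <- cost_consequence(p)
  up <- cost_consequence(apply_override(p, "costs.cost_per_biopsy", 82 * 1.1))
  get_cat <- function(cca, cat, col) cca$costs[[col]][cca$costs$category == cat]
  expect_equal(get_cat(up, "histopathology", "nbi"),
               1.1 * get_cat(base, "histopathology", "nbi"), tolerance = 1e-12)
  for (cat in c("endoscopy_staff_overheads", "treatment_staff_overheads",
                "adverse_events", "capital_equipment")) {
    expect_equal(get_cat(up, cat, "nbi"), get_cat(base, cat, "nbi"),
                 tolerance = 1e-12)
  }
})

test_that("histopathology cost ratio equals the biopsy ratio, discounting-free", {
  for (rate in c(0, 0.035, 0.1)) {
    p <- apply_override(default_parameters(), "economics.discount_rate", rate)
    cca <- cost_consequence(p)
    hist <- cca$costs[cca$costs$category == "histopathology", ]
    expect_equal(hist$nbi / hist$hdwle, 4.24 / 7.6, tolerance = 1e-12)
    expect_equal(hist$rel_diff, 4.24 / 7.6 - 1, tolerance = 1e-12)
  }
})

test_that("hospital perspective books tariffs as income with a margin identity", {
  p <- apply_override(default_parameters(), "economics.perspective", "hospital")
  res_n <- arm_result(p, "nbi")
  res_w <- arm_result(p, "wle")
  for (res in list(res_n, res_w)) {
    expect_false(is.null(res$income))
    tr <- res$trace
    # year 1 income = endoscopy tariff + treatment tariff on treated patients
    treated_frac <- (106 + 48) / 2696 * 0.942
    expect_equal(res$income$income[1],
                 tr$population_exact[1] * (517 + treated_frac * 2101),
                 tolerance = 1e-6)
  }
  # income is tariff-equal across arms, so the margin gap equals the saving
  margin_n <- sum(res_n$income$income) - sum(res_n$costs$cost)
  margin_w <- sum(res_w$income$income) - sum(res_w$costs$cost)
  expect_gt(margin_n, margin_w)  # NBI is the more marginal strategy
  expect_equal(margin_n - margin_w,
               -(sum(res_n$costs$cost) - sum(res_w$costs$cost)),
               tolerance = 1e-6)
})

test_that("identical arms produce identical breakdowns", {
  # pure HD-WLE technology in both arms and no estate to upgrade
  p <- apply_override(default_parameters(), "economics.market_share_nbi", 0)
  p <- apply_override(p, "equipment.olympus_share", 0)
  cca <- cost_consequence(p)
  expect_equal(cca$costs$nbi, cca$costs$hdwle, tolerance = 1e-9)
  expect_equal(cca$outcomes$nbi, cca$outcomes$hdwle, tolerance = 1e-9)
})
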