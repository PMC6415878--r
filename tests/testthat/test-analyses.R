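round_half_up_test <- function(x) floor(x + 0.5)

test_that("base-case biopsy accounting reproduces the published counts", {
  cca <- cost_consequence(default_parameters())
  bio <- cca$outcomes[cca$outcomes$outcome == "biopsies", ]
  expect_equal(round_half_up_test(bio$nbi), 8852892)
  expect_equal(round_half_up_test(bio$hdwle), 15868392)
  expect_equal(round_half_up_test(abs(bio$abs_diff)), 7015500)
  expect_equal(bio$rel_diff, 4.24 / 7.6 - 1, tolerance = 1e-12)
  expect_equal(round(100 * bio$rel_diff, 1), -44.2)
})

test_that("budget-impact rows sum exactly to the cost-consequence totals", {
  p <- default_parameters()
  cca <- cost_consequence(p)
  bi <- budget_impact(p, cca)
  expect_equal(bi$population, c(161657, 193988, 232786, 279343, 335212,
                                402254, 482705))
  expect_equal(sum(bi$cost_nbi), cca$total_nbi, tolerance = 1e-6)
  expect_equal(sum(bi$cost_hdwle), cca$total_hdwle, tolerance = 1e-6)
  expect_equal(sum(bi$difference), cca$total_diff, tolerance = 1e-6)
  # yearly savings grow with the population
  expect_true(all(diff(bi$difference) < 0))
})

test_that("zero unit costs zero out the money columns", {
  p <- default_parameters()
  for (path in c("costs.tariff_endoscopy", "costs.tariff_emr_rfa",
                 "costs.cost_per_biopsy", "costs.ae_costs.stricture",
                 "costs.ae_costs.bleeding", "costs.ae_costs.perforation",
                 "equipment.unit_cost_system", "equipment.unit_cost_scope",
                 "equipment.training_cost_per_day_nbi",
                 "equipment.training_cost_per_day_wle"))
    p <- apply_override(p, path, 0)
  bi <- budget_impact(p)
  expect_equal(bi$cost_nbi, rep(0, 7))
  expect_equal(bi$cost_hdwle, rep(0, 7))
})

test_that("ICER arithmetic and dominance labels are correct", {
  # published scenario-4 inputs: 331.5 mln saved, 1,615 cancer cases avoided
  r <- icer(-331.5e6, 1615)
  expect_equal(r$ratio, -331.5e6 / 1615)
  expect_equal(signif(r$ratio / 1000, 3), -205)
  expect_equal(r$label, "dominant")
  # published scenario-3 inputs: note ratio rounds to -13.6K at 3 s.f.
  r3 <- icer(-417.0e6, 30727)
  expect_equal(signif(r3$ratio / 1000, 3), -13.6)
  expect_equal(icer(-1e6, 0)$label, "cost-saving-equal-effect")
  expect_true(is.na(icer(-1e6, 0)$ratio))
  expect_equal(icer(0, 0)$label, "equivalent")
  expect_equal(icer(5e6, -10)$label, "dominated")
  expect_equal(icer(5e6, 10)$label, "tradeoff")
})

test_that("equal-accuracy scenarios are cost-saving with equal effect", {
  for (id in c(1, 2, 5)) {
    s <- run_scenario(id)
    expect_lt(s$delta_cost, 0)
    expect_equal(s$delta_effect, 0)
    expect_equal(s$icer$label, "cost-saving-equal-effect")
  }
})

test_that("per-lesion scenarios make NBI dominant", {
  s3 <- run_scenario(3)
  expect_lt(s3$delta_cost, 0)
  expect_gt(s3$delta_effect, 0)   # Se 0.890 > 0.791 detects more lesions
  expect_equal(s3$icer$label, "dominant")
  s6 <- run_scenario(6)
  expect_gt(s6$delta_effect, 0)
  s4 <- run_scenario(4)
  expect_gt(s4$delta_effect, 0)   # fewer incident cancers under NBI
  expect_equal(s4$effect_unit, "avoided cancer cases")
})

test_that("invalid scenarios are rejected", {
  expect_error(run_scenario(7), "1-6")
  bad <- tibble::tibble(id = 9L, perspective = "hospital",
                        accuracy_level = "per_patient", long_term = TRUE,
                        description = "x")
  expect_error(run_scenario(bad), "hospital")
})

test_that("a wider biopsy differential strictly increases the saving", {
  p <- default_parameters()
  base <- cost_consequence(p)$total_diff
  wider <- cost_consequence(
    apply_override(p, "procedure.biopsies_nbi", 2.0))$total_diff
  expect_lt(wider, base)
})

test_that("report emitters write the table layouts plus a manifest", {
  dir <- withr::local_tempdir()
  p <- default_parameters()
  cca <- cost_consequence(p)
  write_cca_csv(cca, dir)
  got <- utils::read.csv(file.path(dir, "cost_consequence.csv"))
  expect_equal(got$nbi[got$item == "biopsies"], 8852892)
  expect_equal(got$rel_diff[got$item == "biopsies"], -44.2)
  write_budget_csv(budget_impact(p, cca), dir)
  bi <- utils::read.csv(file.path(dir, "budget_impact.csv"))
  expect_equal(bi$population[bi$year == "Total"], 2087946)
  status <- cca_cli(c("base-case", "--out", dir))
  expect_equal(status, 0L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$command, "base-case")
  expect_true("cost_consequence.csv" %in% unlist(man$files))
  expect_equal(cca_cli(c("scenario", "--scenario", "7", "--out", dir)), 1L)
  expect_equal(cca_cli(c("frobnicate")), 1L)
})

test_that("microsim CLI runs are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  expect_equal(cca_cli(c("microsim", "--n", "500", "--seed", "42", "--out", d1)), 0L)
  expect_equal(cca_cli(c("microsim", "--n", "500", "--seed", "42", "--out", d2)), 0L)
  f1 <- readLines(file.path(d1, "microsim_patients.csv"))
  f2 <- readLines(file.path(d2, "microsim_patients.csv"))
  expect_identical(f1, f2)
})
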