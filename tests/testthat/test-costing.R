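# Costing: micro and HRG methods, scenario machinery, inflation and
# productivity loss.

test_that("zero resource use costs zero under every scenario", {
  rec <- data.frame(qty_theatre_session_p1 = 0, qty_surgeon_min_p1 = 0,
                    qty_gp_visit_p1 = 0, qty_gp_visit_p2 = 0,
                    absence_days = 0)
  for (m in c("micro", "hrg")) {
    out <- cost_patient(rec, scenario = costing_scenario(
      method = m, perspective = "societal"))
    expect_equal(out$intervention_cost, 0)
    expect_equal(out$followup_cost, 0)
    expect_equal(out$societal_cost, 0)
  }
})

test_that("HRG tariffs price the reference episode combinations", {
  sc <- costing_scenario(method = "hrg")
  lf <- data.frame(qty_lf_procedure_p1 = 1, qty_wound_clinic_p1 = 1)
  expect_equal(cost_patient(lf, scenario = sc)$intervention_cost,
               2936 + 196)   # 3132
  co <- data.frame(qty_injection_visit_p1 = 1, qty_manipulation_visit_p1 = 1)
  expect_equal(cost_patient(co, scenario = sc)$intervention_cost,
               1143 + 196)   # 1339
  # micro components the tariff subsumes contribute nothing under hrg
  both <- data.frame(qty_lf_procedure_p1 = 1, qty_theatre_session_p1 = 1,
                     qty_vial_p1 = 1)
  expect_equal(cost_patient(both, scenario = sc)$intervention_cost, 2936)
})

test_that("scenario switches move costs in the right direction only", {
  d <- generate_trial(small_config(n = 120, seed = 17))
  base <- cost_trial(d)
  theatre <- cost_trial(d, scenario = costing_scenario(
    collagenase_setting = "theatre"))
  trainee <- cost_trial(d, scenario = costing_scenario(lf_staff = "trainee"))
  co <- d$arm == "collagenase"
  expect_true(all(theatre$intervention_cost[co] >= base$intervention_cost[co]))
  expect_true(all(theatre$intervention_cost[!co] == base$intervention_cost[!co]))
  expect_true(all(trainee$intervention_cost[!co] <= base$intervention_cost[!co]))
  expect_true(all(trainee$intervention_cost[co] == base$intervention_cost[co]))
})

test_that("societal totals nest NHS/PSS totals for every patient", {
  d <- generate_trial(small_config(n = 120, seed = 18))
  nhs <- cost_trial(d, scenario = costing_scenario(perspective = "nhs_pss"))
  soc <- cost_trial(d, scenario = costing_scenario(perspective = "societal"))
  expect_true(all(nhs$societal_cost == 0))
  expect_true(all(soc$societal_cost >= 0))
  tot_n <- rowSums(nhs[1:3])
  tot_s <- rowSums(soc[1:4])
  expect_true(all(tot_s >= tot_n))
})

test_that("micro-costing is exactly linear in each unit cost", {
  d <- generate_trial(small_config(n = 50, seed = 19))
  units <- default_unit_costs()
  base <- cost_trial(d, units)
  units2 <- units
  i <- units2$category == "physio_visit" & units2$method == "micro"
  units2$unit_cost[i] <- 2 * units2$unit_cost[i]
  doubled <- cost_trial(d, units2)
  extra <- doubled$followup_cost_p1 - base$followup_cost_p1
  expect_equal(extra, d$qty_physio_visit_p1 * 54, tolerance = 1e-12)
})

test_that("unresolved categories and negative quantities are rejected", {
  bad <- data.frame(qty_helicopter_p1 = 1)
  expect_error(cost_trial(bad), "helicopter")
  neg <- data.frame(qty_gp_visit_p1 = -1)
  expect_error(cost_trial(neg), "negative")
})

test_that("vial price override reprices only the drug line", {
  rec <- data.frame(qty_vial_p1 = 2, qty_injection_visit_p1 = 1)
  base <- cost_patient(rec)$intervention_cost
  up <- cost_patient(rec, scenario = costing_scenario(
    collagenase_vial_price = 1000))$intervention_cost
  expect_equal(up - base, 2 * (1000 - 735))
})

test_that("inflation multiplies annual factors and errors on gaps", {
  idx <- c("2018" = 1.02, "2019" = 1.03)
  expect_equal(inflate(100, 2019, 2019, idx), 100)
  expect_equal(inflate(100, 2018, 2020, idx), 105.06)
  expect_equal(inflate(0, 2018, 2020, idx), 0)
  expect_equal(inflate(105.06, 2020, 2018, idx), 100)
  expect_error(inflate(100, 2017, 2019, idx), "2017")
})

test_that("productivity loss is the wage-days product, societal only", {
  expect_equal(productivity_loss(0, 120), 0)
  expect_equal(productivity_loss(5, 100), 500)
  expect_error(productivity_loss(-1, 100), "absence_days")
  d <- generate_trial(trial_config(n_per_arm = 336, seed = 23))
  loss <- productivity_loss(d$absence_days, 100)
  m <- tapply(loss, d$arm, mean)
  # generator calibration: ~487 vs ~138 within Monte-Carlo error
  expect_lt(abs(m[["LF"]] - 487), 4 * 487 / sqrt(1.2) / sqrt(336))
  expect_lt(abs(m[["collagenase"]] - 138), 4 * 138 / sqrt(1.2) / sqrt(336))
})

test_that("unit-cost tables round-trip as text", {
  u <- default_unit_costs()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_unit_costs(u, f)
  u2 <- read_unit_costs(f)
  expect_equal(u2$unit_cost, u$unit_cost)
  expect_equal(u2$category, u$category)
})
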