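# Markov cohort model: transition structure, mass conservation, matrix-power
# equivalence, discounting, and arm comparison.

test_that("transition rows are stochastic and competing-risk scaled", {
  inputs <- markov_inputs(
    recurrence_annual = c(LF = 0.054, collagenase = 0.172),
    life_table = flat_life_table(0.01))
  P <- build_transition_matrix(markov_spec(), inputs, "collagenase",
                               cycle_index = 2, age = 70)
  expect_equal(rowSums(P), setNames(rep(1, 11), rownames(P)))
  # competing-risk arithmetic: recurrence scaled by survival
  expect_equal(P["recovery_initial", "recurrence_initial_new"],
               0.172 * (1 - 0.01))
  expect_equal(sum(P["recovery_initial",
                     c("recurrence_initial_new",
                       "recurrence_initial_settled")]),
               0.17028)
  expect_equal(unname(P[, "dead"]), c(rep(0.01, 10), 1))
})

test_that("no-event and certain-death limits are exact", {
  ne <- no_event_inputs(q = 0)
  P <- build_transition_matrix(markov_spec(), ne, "LF", age = 70)
  expect_equal(P["recovery_initial", "recovery_initial"], 1)
  expect_equal(P["recovery_reint1", "recovery_reint1"], 1)

  certain <- markov_inputs(life_table = flat_life_table(1),
                           cohort = data.frame(age = 66, sex = "M",
                                               weight = 1))
  P1 <- build_transition_matrix(markov_spec(), certain, "LF", age = 70)
  expect_equal(unname(P1[, "dead"]), rep(1, 11))
  tr <- run_cohort(markov_spec(), certain, reward_table(), "LF")
  expect_equal(unname(tr$occupancy[2, "dead"]), 1)
})

test_that("the cohort trace equals entry times matrix powers when homogeneous", {
  inputs <- markov_inputs(life_table = flat_life_table(0.015),
                          cohort = data.frame(age = 66, sex = "M",
                                              weight = 1))
  spec <- markov_spec()
  tr <- run_cohort(spec, inputs, reward_table(), "collagenase")
  P <- build_transition_matrix(spec, inputs, "collagenase", age = 70)
  entry <- tr$occupancy_internal[1, ]
  s <- entry
  for (t in 2:length(tr$cycles)) {
    s <- drop(s %*% P)
    expect_equal(unname(tr$occupancy_internal[t, ]), unname(s),
                 tolerance = 1e-12)
  }
})

test_that("occupancy mass is conserved and death is monotone", {
  m <- markov_cea()
  for (tr in list(m$trace_LF, m$trace_collagenase)) {
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(tr$occupancy >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-15))
  }
})

test_that("the no-event limit reproduces the discounted annuity", {
  u <- 0.8
  rw <- reward_table(year1_utility = c(LF = u, collagenase = u),
                     steady_utility = c(LF = u, collagenase = u),
                     year1_cost = c(LF = 100, collagenase = 100),
                     steady_cost = c(LF = 100, collagenase = 100))
  T_cycles <- 85 - 66
  # undiscounted: u * T
  tr0 <- run_cohort(markov_spec(), no_event_inputs(discount_rate = 0), rw,
                    "LF")
  expect_equal(tail(tr0$cum_qaly, 1), u * T_cycles, tolerance = 1e-12)
  # discounted: geometric annuity with cycle 1 undiscounted
  tr <- run_cohort(markov_spec(), no_event_inputs(discount_rate = 0.035),
                   rw, "LF")
  ann <- sum(1.035^-(0:(T_cycles - 1)))
  expect_equal(tail(tr$cum_qaly, 1), u * ann, tolerance = 1e-12)
})

test_that("stronger discounting lowers lifetime totals", {
  lo <- markov_cea(inputs = markov_inputs(discount_rate = 0.035))
  hi <- markov_cea(inputs = markov_inputs(discount_rate = 0.06))
  i <- nrow(lo$comparison)
  expect_lt(hi$comparison$cost_LF[i], lo$comparison$cost_LF[i])
  expect_lt(hi$comparison$qaly_collagenase[i],
            lo$comparison$qaly_collagenase[i])
})

test_that("identical arm parameters give exactly zero increments", {
  inputs <- markov_inputs(
    recurrence_1y = c(LF = 0.138, collagenase = 0.138),
    recurrence_annual = c(LF = 0.054, collagenase = 0.054))
  rw <- reward_table(
    intervention_cost = c(LF = 2166, collagenase = 2166),
    year1_cost = c(LF = 859, collagenase = 859),
    year1_utility = c(LF = 0.846, collagenase = 0.846),
    steady_cost = c(LF = 470, collagenase = 470),
    steady_utility = c(LF = 0.8715, collagenase = 0.8715))
  m <- markov_cea(inputs = inputs, rewards = rw)
  expect_equal(m$comparison$delta_cost, rep(0, 5))
  expect_equal(m$comparison$delta_qaly, rep(0, 5))
})

test_that("reintervention pathways add intervention costs", {
  with_reint <- markov_cea()$comparison
  no_reint <- markov_cea(inputs = markov_inputs(reintervention_prob = 0))
  # collagenase recurs more, so removing reintervention lowers its lifetime
  # cost by more than LF's
  i <- 5
  expect_lt(no_reint$comparison$cost_collagenase[i],
            with_reint$cost_collagenase[i])
})

test_that("arm comparison arithmetic and horizon validation", {
  mk_trace <- function(cost2, qaly2) {
    structure(list(cycles = 1:2, cum_cost = c(cost2 / 2, cost2),
                   cum_qaly = c(qaly2 / 2, qaly2)),
              class = "cohort_trace")
  }
  cmp <- compare_arms(mk_trace(3479, 1.688), mk_trace(1838, 1.633),
                      horizons = 2, lambdas = c(20000, 30000))
  expect_equal(cmp$delta_cost, 1838 - 3479)     # -1641
  expect_equal(cmp$delta_qaly, 1.633 - 1.688)
  expect_equal(cmp$icer_label, "SW-quadrant")
  expect_error(compare_arms(mk_trace(1, 1), mk_trace(1, 1), horizons = 5),
               "beyond")
  m <- markov_cea()
  expect_error(compare_arms(m$trace_LF, m$trace_collagenase, horizons = 50),
               "beyond")
})

test_that("cumulative outcomes accumulate monotonically", {
  m <- markov_cea()
  for (tr in list(m$trace_LF, m$trace_collagenase)) {
    expect_true(all(diff(tr$cum_cost) >= 0))
    expect_true(all(diff(tr$cum_qaly) >= 0))
  }
})

test_that("model structure validation catches bad specs and inputs", {
  expect_error(markov_spec(states = c("a", "b")), "nine")
  expect_error(markov_inputs(reintervention_prob = 1.4),
               "reintervention_prob")
  expect_error(markov_inputs(cohort = data.frame(age = 90, sex = "M",
                                                 weight = 1)),
               "stop_age")
  expect_error(markov_inputs(cohort = data.frame(age = 66, sex = "M",
                                                 weight = 0.7)),
               "cohort")
  expect_error(build_transition_matrix(markov_spec(), markov_inputs(), "LF",
                                       cycle_index = 0, age = 66),
               "cycle_index")
})
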