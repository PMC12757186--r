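# Synthetic trial generator: reproducibility, calibration, structural zeros,
# the missing-at-random masking mechanism, and text round trips.

test_that("identical config and seed give a bit-identical dataset", {
  a <- generate_trial(small_config(seed = 5))
  b <- generate_trial(small_config(seed = 5))
  expect_identical(a, b)
  c <- generate_trial(small_config(seed = 6))
  expect_false(identical(a, c))
})

test_that("degenerate configs behave exactly as specified", {
  # no death hazard -> nobody dies
  d0 <- generate_trial(small_config(
    death_hazard = c(LF = 0, collagenase = 0)))
  expect_true(all(is.na(d0$death_time)))
  # zero utility dispersion -> utilities equal their arm/time means
  dz <- generate_trial(small_config(utility_sd = 0,
                                    death_hazard = c(LF = 0, collagenase = 0)))
  expect_true(all(dz$utility_2[dz$arm == "LF"] == 0.715))
  expect_true(all(dz$utility_1[dz$arm == "collagenase"] == 0.791))
})

test_that("recurrence proportions converge to the configured probabilities", {
  d <- generate_trial(trial_config(n_per_arm = 5000, seed = 21,
                                   death_hazard = c(LF = 0, collagenase = 0)))
  p <- tapply(d$recurrence_1y, d$arm, mean)
  se <- sqrt(c(0.138 * 0.862, 0.172 * 0.828) / 5000)
  expect_lt(abs(p[["LF"]] - 0.138), 3 * se[1])
  expect_lt(abs(p[["collagenase"]] - 0.172), 3 * se[2])
})

test_that("empirical means track configured utility and cost calibration", {
  d <- generate_trial(trial_config(n_per_arm = 336, seed = 42))
  co <- cost_trial(d)
  mint <- tapply(co$intervention_cost, d$arm, mean)
  # Monte-Carlo tolerances ~ 4 standard errors of the component mixtures
  expect_lt(abs(mint[["LF"]] - 2166), 60)
  expect_lt(abs(mint[["collagenase"]] - 984), 5)
  u2 <- tapply(d$utility_2, d$arm, mean, na.rm = TRUE)
  expect_lt(abs(u2[["LF"]] - 0.715), 4 * 0.16 / sqrt(336))
  expect_lt(abs(u2[["collagenase"]] - 0.776), 4 * 0.16 / sqrt(336))
  # costs are right-skewed
  expect_gt(sample_skewness(co$intervention_cost[d$arm == "LF"]), 0)
  expect_gt(sample_skewness(co$followup_cost_p1), 0)
})

test_that("nothing is accrued after death", {
  d <- generate_trial(small_config(n = 400, seed = 3,
                                   death_hazard = c(LF = 0.4,
                                                    collagenase = 0.4)))
  tt <- attr(d, "followup_times")
  dead <- which(!is.na(d$death_time))
  expect_gt(length(dead), 10)
  for (i in dead) {
    after <- which(tt >= d$death_time[i])
    u <- as.numeric(d[i, paste0("utility_", after)])
    expect_true(all(u == 0))
    if (d$death_time[i] <= 1) {
      expect_equal(as.numeric(d[i, grep("_p2$", names(d))]),
                   rep(0, length(grep("_p2$", names(d)))))
    }
  }
})

test_that("life table generation matches its closed forms", {
  # flat hazard
  lt <- generate_life_table(0.01, 1, max_age = 85)
  expect_true(all(lt$qx == 0.01))
  # geometric growth ratio over ten years
  lt2 <- generate_life_table(0.01, 1.1, max_age = 85, start_age = 40)
  q0 <- life_table_q(lt2, 40, "M")
  q10 <- life_table_q(lt2, 50, "M")
  expect_equal(q10 / q0, 1.1^10, tolerance = 1e-12)
  # certain death boundary
  lt3 <- generate_life_table(1, 1.05, max_age = 30, start_age = 20)
  expect_true(all(lt3$qx == 1))
  expect_error(generate_life_table(0.01, 1.1, max_age = 10, start_age = 18),
               "max_age")
  expect_error(generate_life_table(0, 1.1, max_age = 85), "base_q")
})

test_that("MAR masking respects its logistic specification", {
  # all-minus-infinity coefficients: nothing masked
  d <- generate_trial(small_config(n = 80, seed = 2))
  spec0 <- missingness_spec(c(intercept = -Inf))
  expect_identical(apply_missingness(d, spec0, seed = 1), d)

  # intercept-only at logit 0: half of maskable cells masked
  big <- generate_trial(trial_config(n_per_arm = 1000, seed = 8,
                                     death_hazard = c(LF = 0,
                                                      collagenase = 0)))
  m <- apply_missingness(big, missingness_spec(c(intercept = 0),
                                               targets = "utilities"),
                         seed = 4)
  cells <- as.matrix(m[paste0("utility_", 2:7)])
  frac <- mean(is.na(cells))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / length(cells)))

  # positive age coefficient: masking increases across age terciles
  m2 <- apply_missingness(big,
                          missingness_spec(c(intercept = qlogis(0.3),
                                             age_per_decade = 0.8),
                                           targets = "utilities"),
                          seed = 5)
  terc <- cut(m2$age, quantile(m2$age, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  fr <- tapply(is.na(m2$utility_6), terc, mean)
  expect_true(all(diff(fr) > 0))
})

test_that("masking never touches death-censored structural zeros", {
  d <- generate_trial(small_config(n = 300, seed = 13,
                                   death_hazard = c(LF = 0.5,
                                                    collagenase = 0.5)))
  heavy <- missingness_spec(c(intercept = qlogis(0.9)))
  m <- apply_missingness(d, heavy, seed = 2)
  tt <- attr(d, "followup_times")
  for (i in which(!is.na(d$death_time))) {
    after <- which(tt >= d$death_time[i])
    expect_true(all(as.numeric(m[i, paste0("utility_", after)]) == 0))
  }
})

test_that("MNAR missingness drivers are rejected", {
  expect_error(missingness_spec(c(intercept = 0, utility_6 = 1)), "MNAR")
  expect_error(missingness_spec(c(followup_cost_p1 = 0.5)), "MNAR")
})

test_that("invalid configs fail naming the offending field", {
  expect_error(trial_config(n_per_arm = 0), "n_per_arm")
  expect_error(trial_config(followup_times = c(0.5, 1)), "followup_times")
  expect_error(trial_config(recurrence_prob_1y = c(LF = 1.2,
                                                   collagenase = 0.1)),
               "recurrence_prob_1y")
  expect_error(trial_config(utility_sd = -1), "utility_sd")
})

test_that("patient and life tables round-trip losslessly as text", {
  d <- apply_missingness(generate_trial(small_config(n = 40, seed = 9)),
                         seed = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_patient_table(d, f)
  d2 <- read_patient_table(f)
  expect_equal(attr(d2, "followup_times"), attr(d, "followup_times"))
  for (cl in names(d)) expect_equal(d2[[cl]], d[[cl]], tolerance = 0)

  lt <- generate_life_table(4e-4, 1.083, max_age = 100, female_factor = 0.6)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_life_table(lt, f2)
  expect_equal(read_life_table(f2)$qx, lt$qx, tolerance = 0)
})
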