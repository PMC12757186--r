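# Chained-equation multiple imputation and Rubin-rules pooling.

make_masked_data <- function(n = 150, seed = 31, mask_seed = 32) {
  cfg <- small_config(n = n, seed = seed)
  d <- apply_missingness(generate_trial(cfg), cfg$missingness,
                         seed = mask_seed)
  assemble_cea_data(d)
}

test_that("a complete dataset yields m identical copies", {
  d <- generate_trial(small_config(n = 40, seed = 27))
  adf <- assemble_cea_data(d)
  stack <- mice_impute(adf, mi_config(m = 3, seed = 1))
  expect_length(stack$imputations, 3)
  expect_identical(stack$imputations[[1]], stack$imputations[[3]])
  # recurrence for patients dead before one year is fixed at zero
  expect_false(anyNA(stack$imputations[[1]]$recurrence_1y))
})

test_that("imputation completes all cells but never alters observed ones", {
  adf <- make_masked_data()
  stack <- mice_impute(adf, mi_config(m = 2, iterations = 3, seed = 7))
  vars <- stack$imputed_vars
  expect_gt(length(vars), 0)
  for (j in 1:2) {
    comp <- stack$imputations[[j]]
    for (v in vars) {
      expect_false(anyNA(comp[[v]]))
      obs <- !is.na(adf[[v]])
      expect_identical(comp[[v]][obs], adf[[v]][obs])
    }
  }
})

test_that("death-censored zeros survive imputation in every copy", {
  cfg <- small_config(n = 200, seed = 33,
                      death_hazard = c(LF = 0.3, collagenase = 0.3))
  d <- apply_missingness(generate_trial(cfg), cfg$missingness, seed = 34)
  adf <- assemble_cea_data(d)
  tt <- attr(adf, "followup_times")
  stack <- mice_impute(adf, mi_config(m = 3, iterations = 2, seed = 8))
  dead <- which(!is.na(adf$death_time))
  expect_gt(length(dead), 5)
  for (comp in stack$imputations) {
    for (i in dead) {
      after <- which(tt >= adf$death_time[i])
      after <- after[after > 1]
      expect_true(all(comp[i, paste0("utility_", after)] == 0))
      if (adf$death_time[i] <= 1) {
        expect_identical(comp$followup_cost_p2[i], 0)
      }
    }
  }
})

test_that("the MI run is deterministic given its seed", {
  adf <- make_masked_data(n = 80)
  s1 <- mice_impute(adf, mi_config(m = 2, iterations = 2, seed = 99))
  s2 <- mice_impute(adf, mi_config(m = 2, iterations = 2, seed = 99))
  expect_identical(s1$imputations, s2$imputations)
})

test_that("a fully missing variable is an error", {
  adf <- make_masked_data(n = 40)
  adf$pem_score <- NA_real_
  expect_error(mice_impute(adf, mi_config(m = 2)), "pem_score")
})

test_that("Rubin's rules match hand computation and are order-invariant", {
  p <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$between, 2)
  expect_equal(p$variance, 1 + 1.5 * 2)   # within + (1 + 1/m) * between
  expect_equal(p$df, (2 - 1) * (1 + 1 / 3)^2)

  est <- c(0.4, 0.9, 0.1, 0.6)
  v <- c(0.02, 0.05, 0.04, 0.03)
  o <- sample(4)
  expect_equal(rubin_pool(est, v), rubin_pool(est[o], v[o]))

  # zero between-imputation variance: pooled = common value, df infinite
  z <- rubin_pool(c(2, 2, 2), c(0.5, 0.7, 0.6))
  expect_equal(z$estimate, 2)
  expect_equal(z$variance, 0.6)
  expect_identical(z$df, Inf)
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("imputation stacks round-trip through the stacked text format", {
  adf <- make_masked_data(n = 30)
  stack <- mice_impute(adf, mi_config(m = 2, iterations = 1, seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mi_stack(stack, f)
  back <- read_mi_stack(f)
  expect_equal(back$m, 2)
  expect_equal(back$imputations[[2]]$followup_cost_p1,
               stack$imputations[[2]]$followup_cost_p1, tolerance = 1e-6)
})

test_that("missingness screening reports association tests", {
  adf <- make_masked_data(n = 120)
  sc <- missingness_screen(adf)
  expect_true(all(c("variable", "candidate", "test", "p_value") %in% names(sc)))
  expect_gt(nrow(sc), 0)
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1, na.rm = TRUE))
})

test_that("MCAR masking leaves the pooled incremental QALYs unbiased", {
  # one large complete dataset; the full-data SUR estimate is the reference
  cfg <- trial_config(n_per_arm = 1000, seed = 301,
                      death_hazard = c(LF = 0, collagenase = 0))
  full <- generate_trial(cfg)
  adf_full <- assemble_cea_data(full)
  ref <- fit_sur(dupcea:::finalize_horizon(adf_full, 1))$delta["delta_qaly"]
  mcar <- missingness_spec(c(intercept = qlogis(0.2)), targets = "utilities")
  est <- vapply(1:50, function(r) {
    masked <- apply_missingness(full, mcar, seed = 400 + r)
    stack <- mice_impute(assemble_cea_data(masked),
                         mi_config(m = 2, iterations = 2, seed = 500 + r))
    mean(vapply(stack$imputations, function(d) {
      fit_sur(dupcea:::finalize_horizon(d, 1))$delta["delta_qaly"]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(est) - ref), 0.005)
})
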