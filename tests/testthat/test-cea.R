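# Within-trial CEA machinery: SUR, NHB/ICER, bootstrap, CEAC, price
# threshold, and the cea_trial fitting interface.

test_that("SUR with common regressors equals per-equation least squares", {
  d <- make_linear_cea_data(150, seed = 41)
  fit <- fit_sur(d)
  ols_c <- lm(cost ~ arm + baseline_cost + baseline_utility, d)
  ols_q <- lm(qaly ~ arm + baseline_cost + baseline_utility, d)
  expect_equal(unname(fit$coefficients[, "cost"]), unname(coef(ols_c)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[, "effect"]), unname(coef(ols_q)),
               tolerance = 1e-8)
})

test_that("SUR recovers generating coefficients", {
  # noiseless: exact recovery
  d0 <- make_linear_cea_data(100, sd_cost = 0, sd_qaly = 0, seed = 42)
  f0 <- fit_sur(d0)
  expect_equal(unname(f0$delta["delta_cost"]), -1100, tolerance = 1e-8)
  expect_equal(unname(f0$delta["delta_qaly"]), -0.003, tolerance = 1e-10)
  # noisy, large n: within 3 standard errors of truth
  d <- make_linear_cea_data(5000, seed = 43)
  f <- fit_sur(d)
  expect_lt(abs(f$delta["delta_cost"] + 1100),
            3 * sqrt(f$delta_vcov[1, 1]))
  expect_lt(abs(f$delta["delta_qaly"] + 0.003),
            3 * sqrt(f$delta_vcov[2, 2]))
})

test_that("singular designs are rejected", {
  d <- make_linear_cea_data(50, seed = 44)
  d$baseline_cost <- 1
  expect_error(fit_sur(d), "singular")
})

test_that("NHB matches its definition and rejects bad thresholds", {
  expect_equal(nhb(-1090, -0.003, 20000), 0.0515)
  expect_equal(nhb(0, 0, 30000), 0)
  expect_equal(nhb(-1490, -0.011, 30000), 0.0386667, tolerance = 1e-6)
  expect_equal(nmb(-1090, -0.003, 20000), 20000 * 0.0515)
  expect_error(nhb(-1090, -0.003, 0), "wtp")
  expect_error(nhb(-1090, -0.003, -1), "wtp")
})

test_that("ICER quadrant labelling covers the plane", {
  sw <- icer(-1212, -0.048)
  expect_equal(sw$ratio, 25250)
  expect_equal(sw$label, "SW-quadrant")
  expect_equal(icer(-100, 0.01)$label, "dominant")
  expect_equal(icer(100, -0.01)$label, "dominated")
  expect_equal(icer(100, 0.01)$label, "NE-quadrant")
  ze <- icer(-100, 0)
  expect_equal(ze$label, "dominant")
  expect_true(is.na(ze$ratio))
})

test_that("NHB sign agrees with the ICER-threshold decision everywhere", {
  lambda <- 20000
  grid <- expand.grid(dc = c(-1500, -1, 0, 1, 1500),
                      de = c(-0.2, -0.001, 0, 0.001, 0.2))
  for (i in seq_len(nrow(grid))) {
    dc <- grid$dc[i]; de <- grid$de[i]
    nh <- nhb(dc, de, lambda)
    if (nh == 0) next   # boundary: both rules indifferent
    expect_identical(nh > 0, dupcea:::icer_decision(dc, de, lambda),
                     info = sprintf("dc=%g de=%g", dc, de))
  }
})

test_that("CEAC has the right limits, monotonicity and complementarity", {
  # all draws dominant for collagenase
  dom <- ceac_curve(rep(-100, 50), rep(0.01, 50), c(0, 10000, 30000))
  expect_true(all(dom$p_ce == 1))
  # SW-quadrant draws: non-increasing in lambda
  set.seed(45)
  dc <- -rexp(500, 1 / 1000); de <- -rexp(500, 1 / 0.05)
  sw <- ceac_curve(dc, de, seq(0, 100000, 1000))
  expect_true(all(diff(sw$p_ce) <= 1e-12))
  # single draw crosses at dc/de
  one <- ceac_curve(-1090, -0.003, c(300000, 400000))
  expect_equal(one$p_ce, c(1, 0))
  # two-alternative complementarity
  both <- ceac_curve(rnorm(2000, -500, 800), rnorm(2000, -0.01, 0.05),
                     seq(500, 50000, 500))
  expect_equal(both$p_ce + both$p_comparator, rep(1, nrow(both)))
})

test_that("bootstrap collapses to the point estimate without noise", {
  d0 <- make_linear_cea_data(60, sd_cost = 0, sd_qaly = 0, seed = 46)
  b <- bootstrap_cea(list(d0), bootstrap_config(reps_per_imputation = 5,
                                                seed = 2))
  expect_equal(b$delta_cost, rep(-1100, 5), tolerance = 1e-7)
  expect_equal(b$delta_qaly, rep(-0.003, 5), tolerance = 1e-9)
})

test_that("bootstrap pools m x reps draws and is seed-deterministic", {
  sets <- lapply(1:3, function(j) make_linear_cea_data(60, seed = 50 + j))
  b1 <- bootstrap_cea(sets, bootstrap_config(10, seed = 5))
  b2 <- bootstrap_cea(sets, bootstrap_config(10, seed = 5))
  expect_equal(nrow(b1), 30)
  expect_identical(b1$delta_cost, b2$delta_cost)
  expect_setequal(unique(b1$imp), 1:3)
})

test_that("price threshold search is monotone and handles limits", {
  sets <- lapply(1:2, function(j) {
    make_linear_cea_data(150, delta_cost = -1100, delta_qaly = -0.02,
                         seed = 60 + j)
  })
  pt <- price_threshold(sets, base_price = 735, lambda = 20000,
                        price_grid = seq(0, 3000, 50))
  expect_true(all(diff(pt$grid$nhb) < 0))          # strictly decreasing
  expect_equal(pt$status, "within_grid")
  expect_true(pt$threshold > 0)
  # each extra pound of vial price adds >= 1 pound per collagenase patient
  slope <- diff(pt$grid$nhb) / diff(pt$grid$price) * -20000
  expect_true(all(slope >= 1 - 1e-6))
  # enormous willingness-to-pay on QALY-losing data: below grid
  pt2 <- price_threshold(sets, base_price = 735, lambda = 1e9,
                         price_grid = seq(0, 3000, 500))
  expect_equal(pt2$status, "below_grid")
  expect_true(is.na(pt2$threshold))
  expect_error(price_threshold(sets, 735, 20000, c(10, 5)), "price_grid")
})

test_that("pooled point estimates equal the mean of per-imputation fits", {
  cfg <- small_config(n = 90, seed = 71)
  dat <- apply_missingness(generate_trial(cfg), cfg$missingness, seed = 72)
  fit <- cea_trial(dat, mi = mi_config(m = 4, iterations = 2),
                   boot = bootstrap_config(5), horizons = 1, seed = 3)
  res <- fit$results[["1"]]
  expect_equal(res$delta_cost, mean(res$per_imputation[, 1]))
  expect_equal(res$delta_qaly, mean(res$per_imputation[, 2]))
})

test_that("cea_trial returns a coherent fitted object", {
  cfg <- small_config(n = 70, seed = 73)
  dat <- apply_missingness(generate_trial(cfg), cfg$missingness, seed = 74)
  fit <- cea_trial(dat, mi = mi_config(m = 2, iterations = 2),
                   boot = bootstrap_config(10), seed = 4)
  expect_s3_class(fit, "cea_fit")
  cf <- coef(fit)
  expect_equal(dim(cf), c(2, 2))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= ci[, 2]))
  expect_true(all(fit$results[["1"]]$ceac$p_ce >= 0 &
                    fit$results[["1"]]$ceac$p_ce <= 1))
  expect_output(print(fit), "Incremental cost")

  # complete-case analysis drops incomplete rows and reports its n
  cc <- cea_trial(dat, complete_case = TRUE, mi = NULL,
                  boot = bootstrap_config(10), horizons = 1, seed = 4)
  expect_lt(cc$n, nrow(dat))
  expect_equal(cc$m, 1)
})
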