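# Shared fixtures, all generated in code.

small_config <- function(n = 60, seed = 11, ...) {
  trial_config(n_per_arm = n, seed = seed, ...)
}

# Analysis-ready linear data with exactly known incremental effects:
# cost and QALY are linear in arm and baselines with correlated errors, so
# the SUR treatment coefficients have known truth.
make_linear_cea_data <- function(n_per_arm, delta_cost = -1100,
                                 delta_qaly = -0.003, sd_cost = 600,
                                 sd_qaly = 0.05, rho = -0.3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_arm
  arm <- factor(rep(c("LF", "collagenase"), each = n_per_arm),
                levels = c("LF", "collagenase"))
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  baseline_cost <- rgamma(n, 2, scale = 75)
  baseline_utility <- runif(n, 0.5, 1)
  col <- as.numeric(arm == "collagenase")
  data.frame(
    arm = arm, baseline_cost = baseline_cost,
    baseline_utility = baseline_utility,
    cost = 2700 + 0.4 * baseline_cost + delta_cost * col + sd_cost * z1,
    qaly = 0.05 + 0.9 * baseline_utility + delta_qaly * col + sd_qaly * z2,
    qty_vial = col
  )
}

# A flat life table with exact hazard q for closed-form Markov checks.
flat_life_table <- function(q, max_age = 100, start_age = 18) {
  ages <- start_age:max_age
  structure(data.frame(age = rep(ages, 2),
                       sex = rep(c("F", "M"), each = length(ages)),
                       qx = q),
            class = c("life_table", "data.frame"))
}

no_event_inputs <- function(q = 0, stop_age = 85, age = 66,
                            discount_rate = 0.035) {
  markov_inputs(
    recurrence_1y = c(LF = 0, collagenase = 0),
    recurrence_annual = c(LF = 0, collagenase = 0),
    reintervention_prob = 0,
    life_table = flat_life_table(q),
    cohort = data.frame(age = age, sex = "M", weight = 1),
    discount_rate = discount_rate, stop_age = stop_age)
}

fixed_prior <- function(value) list(family = "fixed", value = value)

sample_skewness <- function(x) {
  m <- mean(x)
  s <- sd(x)
  mean((x - m)^3) / s^3
}
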