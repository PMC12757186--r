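# Seed-reproducible synthetic two-arm trial data with the statistical
# structure the downstream analyses assume: right-skewed resource
# use/costs, left-skewed bounded utilities with arm-specific trajectories
# (a sharp two-week dip after surgery, a mild dip then slow decline after
# injection), rare deaths, one-year recurrence, and covariate-driven
# missing-at-random masking that the imputation model can exploit.

UTILITY_FLOOR <- -0.594

FOLLOWUP_CATEGORIES <- c("gp_visit", "physio_visit", "outpatient_visit",
                         "medication")
INTERVENTION_CATEGORIES <- c("lf_procedure", "theatre_session", "surgeon_min",
                             "lf_consumable", "wound_clinic", "vial",
                             "injection_visit", "manipulation_visit",
                             "colla_consumable")

#' Default per-arm utility trajectory means
#'
#' Expected utility at each scheduled follow-up (baseline, 2 and 6 weeks, 3
#' and 6 months, 1 and 2 years). Surgery shows a sharp early dip (0.794 to
#' 0.715 at two weeks) then recovery and a stable plateau; injection shows a
#' mild dip (0.791 to 0.776) then a slow decline, ending about 0.044 lower at
#' two years.
#'
#' @return A 2 x 7 matrix, rows "LF" and "collagenase".
#' @export
default_utility_means <- function() {
  m <- rbind(
    LF          = c(0.794, 0.715, 0.770, 0.840, 0.840, 0.845, 0.850),
    collagenase = c(0.791, 0.776, 0.800, 0.830, 0.825, 0.820, 0.806)
  )
  colnames(m) <- c("t0", "t2wk", "t6wk", "t3m", "t6m", "t1y", "t2y")
  m
}

#' Default resource-use quantity model
#'
#' One row per arm x period x cost category giving the expected quantity and
#' a gamma shape (`NA` shape means the quantity is deterministic, e.g. one
#' theatre session per operation). Category means are calibrated so that, at
#' the default unit costs, expected intervention costs are 2166 GBP (LF) and
#' 984 GBP (collagenase) and follow-up care costs roughly 521/613 GBP in year
#' one and 393/271 GBP in year two.
#'
#' @return Data frame with columns `arm`, `period`, `category`, `mean_qty`,
#'   `shape`.
#' @export
default_cost_components <- function() {
  df <- rbind(
    data.frame(arm = "LF", period = 1,
               category = c("lf_procedure", "theatre_session", "surgeon_min",
                            "lf_consumable", "wound_clinic"),
               mean_qty = c(1, 1, 90, 7.578, 1),
               shape = c(NA, NA, 4, 4, NA)),
    data.frame(arm = "collagenase", period = 1,
               category = c("vial", "injection_visit", "manipulation_visit",
                            "colla_consumable"),
               mean_qty = c(1, 1, 1, 4.142857),
               shape = c(NA, NA, NA, 4)),
    data.frame(arm = "LF", period = 1, category = FOLLOWUP_CATEGORIES,
               mean_qty = c(1.5, 4.0, 2.0, 3.3), shape = 1.5),
    data.frame(arm = "collagenase", period = 1, category = FOLLOWUP_CATEGORIES,
               mean_qty = c(1.4, 0.8, 4.5, 2.5), shape = 1.5),
    data.frame(arm = "LF", period = 2, category = FOLLOWUP_CATEGORIES,
               mean_qty = c(1.0, 1.5, 2.2, 3.9), shape = 1.5),
    data.frame(arm = "collagenase", period = 2, category = FOLLOWUP_CATEGORIES,
               mean_qty = c(1.0, 0.5, 1.6, 3.6), shape = 1.5)
  )
  df$arm <- as.character(df$arm)
  df
}

#' Missing-at-random masking specification
#'
#' Logistic model for the probability that an observable cell is masked.
#' Coefficients may reference only covariates that are always observed
#' (baseline and administrative fields); referencing a post-baseline outcome
#' would make the mechanism missing-not-at-random and is rejected.
#'
#' Allowed coefficient names: `intercept`, `age_per_decade` (per decade above
#' 65), `sex_M`, `arm_collagenase`, `baseline_utility` (per unit above 0.8).
#'
#' @param coefficients Named numeric vector of logit coefficients.
#' @param targets Which fields are maskable: any of `"utilities"` (post-
#'   baseline utility scores), `"followup_costs"` (follow-up resource-use
#'   quantities, masked per period), `"pem_score"`, `"recurrence_1y"`.
#' @return A `missingness_spec`.
#' @export
missingness_spec <- function(coefficients = c(intercept = stats::qlogis(0.15),
                                              age_per_decade = 0.3),
                             targets = c("utilities", "followup_costs",
                                         "pem_score", "recurrence_1y")) {
  allowed <- c("intercept", "age_per_decade", "sex_M", "arm_collagenase",
               "baseline_utility")
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad) > 0) {
    stop_field("missingness", paste0(
      "coefficient(s) ", paste(sQuote(bad), collapse = ", "),
      " are not always-observed covariates; a mechanism driven by a ",
      "post-baseline outcome would be missing-not-at-random (MNAR). ",
      "Allowed: ", paste(allowed, collapse = ", ")))
  }
  targets <- match.arg(targets, several.ok = TRUE)
  structure(list(coefficients = coefficients, targets = targets),
            class = "missingness_spec")
}

#' Synthetic trial configuration
#'
#' Parameters of the synthetic patient-level data generator. Defaults emulate
#' a two-arm, 336-patients-per-arm hand-surgery trial with follow-up at 2 and
#' 6 weeks, 3 and 6 months, 1 and 2 years.
#'
#' @param n_per_arm Patients per arm (default 336).
#' @param followup_times Follow-up schedule in years, strictly increasing and
#'   starting at 0.
#' @param utility_means 2 x length(followup_times) matrix of expected
#'   utilities (rows "LF", "collagenase"); see [default_utility_means()].
#' @param utility_sd Dispersion of utilities around their mean before
#'   censoring into `[utility_floor, 1]`.
#' @param utility_floor Lower bound of the utility scale (default -0.594, the
#'   conventional floor of the UK three-level value set).
#' @param frailty_cor Correlation loading of a shared patient-level frailty
#'   factor on utility errors; induces the within-patient cost-utility
#'   correlation that joint (SUR) estimation exists to exploit.
#' @param cost_frailty Log-scale frailty loading on stochastic resource-use
#'   quantities (mean-preserving).
#' @param cost_components Resource-use quantity model; see
#'   [default_cost_components()].
#' @param death_hazard Named per-arm annual death probability.
#' @param recurrence_prob_1y Named per-arm probability of contracture
#'   recurrence by one year.
#' @param absence_days_mean Named per-arm mean work days lost.
#' @param baseline_cost_mean,baseline_cost_shape Gamma parameters for
#'   pre-treatment resource-use cost (an adjustment covariate).
#' @param missingness A [missingness_spec()].
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   dataset.
#' @return A validated `trial_config`.
#' @export
trial_config <- function(n_per_arm = 336,
                         followup_times = c(0, 2/52, 6/52, 0.25, 0.5, 1, 2),
                         utility_means = default_utility_means(),
                         utility_sd = 0.16,
                         utility_floor = UTILITY_FLOOR,
                         frailty_cor = 0.35,
                         cost_frailty = 0.25,
                         cost_components = default_cost_components(),
                         death_hazard = c(LF = 0.0015, collagenase = 0.0119),
                         recurrence_prob_1y = c(LF = 0.138, collagenase = 0.172),
                         absence_days_mean = c(LF = 4.87, collagenase = 1.38),
                         baseline_cost_mean = 150,
                         baseline_cost_shape = 1.5,
                         missingness = missingness_spec(),
                         seed = 1L) {
  check_count(n_per_arm, "n_per_arm", min = 1)
  if (length(followup_times) < 2 || followup_times[1] != 0 ||
      any(diff(followup_times) <= 0)) {
    stop_field("followup_times", "must be strictly increasing and start at 0")
  }
  if (!is.matrix(utility_means) ||
      !identical(rownames(utility_means), ARM_LEVELS) ||
      ncol(utility_means) != length(followup_times)) {
    stop_field("utility_means",
               "must be a matrix with rows LF, collagenase and one column per follow-up time")
  }
  if (any(utility_means < utility_floor) || any(utility_means > 1)) {
    stop_field("utility_means", sprintf("must lie in [%g, 1]", utility_floor))
  }
  check_nonneg(utility_sd, "utility_sd")
  if (abs(frailty_cor) > 1) stop_field("frailty_cor", "must be in [-1, 1]")
  check_prob(death_hazard, "death_hazard")
  check_prob(recurrence_prob_1y, "recurrence_prob_1y")
  for (nm in c("death_hazard", "recurrence_prob_1y", "absence_days_mean")) {
    v <- get(nm)
    if (!all(ARM_LEVELS %in% names(v))) {
      stop_field(nm, "must be named with LF and collagenase")
    }
  }
  check_nonneg(cost_components$mean_qty, "cost_components$mean_qty")
  if (!inherits(missingness, "missingness_spec")) {
    stop_field("missingness", "must be a missingness_spec()")
  }
  structure(list(
    n_per_arm = as.integer(n_per_arm), followup_times = followup_times,
    utility_means = utility_means, utility_sd = utility_sd,
    utility_floor = utility_floor, frailty_cor = frailty_cor,
    cost_frailty = cost_frailty, cost_components = cost_components,
    death_hazard = death_hazard, recurrence_prob_1y = recurrence_prob_1y,
    absence_days_mean = absence_days_mean,
    baseline_cost_mean = baseline_cost_mean,
    baseline_cost_shape = baseline_cost_shape,
    missingness = missingness, seed = as.integer(seed)
  ), class = "trial_config")
}

# Location of a normal censored into [lower, upper] whose censored mean equals
# `target`; keeps empirical utility means on target despite the bounds.
cn_location <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  if (target <= lower) return(lower - 12 * sd)
  if (target >= upper) return(upper + 12 * sd)
  cmean <- function(m) {
    a <- (lower - m) / sd
    b <- (upper - m) / sd
    lower * stats::pnorm(a) + upper * (1 - stats::pnorm(b)) +
      m * (stats::pnorm(b) - stats::pnorm(a)) -
      sd * (stats::dnorm(b) - stats::dnorm(a))
  }
  stats::uniroot(function(m) cmean(m) - target,
                 lower = target - 12 * sd, upper = target + 12 * sd,
                 tol = 1e-12)$root
}

qty_col <- function(category, period) sprintf("qty_%s_p%d", category, period)

#' Generate a synthetic patient-level trial dataset
#'
#' Draws a complete (no missingness) two-arm dataset under a
#' [trial_config()]: demographics, baseline cost, per-follow-up utilities
#' (censored normal around arm- and time-specific means, correlated within
#' patient through a shared frailty factor), gamma-distributed resource-use
#' quantities per cost category and period (right-skewed, frailty-scaled),
#' exponential death times, and a one-year recurrence flag. Utilities at
#' follow-ups on or after the death time and resource use in periods starting
#' after death are structural zeros, not missing values. Use
#' [apply_missingness()] to mask cells afterwards.
#'
#' @param config A [trial_config()].
#' @return A `trial_data` data frame, one row per patient, with attribute
#'   `followup_times`. Utility columns are `utility_1` ... `utility_K`
#'   (column k is follow-up time k); resource quantities are
#'   `qty_<category>_p<period>`.
#' @examples
#' dat <- generate_trial(trial_config(n_per_arm = 20, seed = 7))
#' table(dat$arm)
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "trial_config")) {
    stop_field("config", "must be a trial_config()")
  }
  with_seed(config$seed, {
    n <- 2L * config$n_per_arm
    arm <- factor(rep(ARM_LEVELS, each = config$n_per_arm),
                  levels = ARM_LEVELS)
    tt <- config$followup_times
    K <- length(tt)
    horizon <- max(tt)

    # demographics (trial marginals are not public: configurable placeholders)
    age <- stats::qnorm(stats::runif(n, stats::pnorm(18, 66, 8),
                                     stats::pnorm(84, 66, 8)), 66, 8)
    sex <- ifelse(stats::runif(n) < 0.8, "M", "F")
    num_cords <- 1L + stats::rpois(n, 0.6)
    pem_score <- pmin(100, pmax(0, stats::rnorm(n, 35, 15)))
    frailty <- stats::rnorm(n)

    shape_b <- config$baseline_cost_shape
    baseline_cost <- stats::rgamma(n, shape = shape_b,
                                   scale = config$baseline_cost_mean / shape_b) *
      exp(config$cost_frailty * frailty - config$cost_frailty^2 / 2)

    # death: exponential with the arm's annual probability; only deaths inside
    # the trial window are observed
    haz <- config$death_hazard[as.character(arm)]
    rate <- -log(1 - haz)
    death_time <- ifelse(rate > 0, stats::rexp(n) / pmax(rate, 1e-300), Inf)
    death_time[death_time > horizon] <- NA_real_

    # utilities: censored normal, location solved so the censored mean hits the
    # target; errors share the patient frailty (negative loading: sicker
    # patients report lower utility and use more resources)
    rho <- config$frailty_cor
    u <- matrix(NA_real_, n, K)
    for (k in seq_len(K)) {
      for (a in ARM_LEVELS) {
        rows <- which(arm == a)
        m <- config$utility_means[a, k]
        if (config$utility_sd == 0) {
          u[rows, k] <- m
        } else {
          loc <- cn_location(m, config$utility_sd, config$utility_floor, 1)
          e <- -rho * frailty[rows] +
            sqrt(1 - rho^2) * stats::rnorm(length(rows))
          u[rows, k] <- pmin(1, pmax(config$utility_floor,
                                     loc + config$utility_sd * e))
        }
      }
    }
    # structural zeros at and after death
    for (k in seq_len(K)) {
      dead <- !is.na(death_time) & tt[k] >= death_time
      u[dead, k] <- 0
    }
    colnames(u) <- paste0("utility_", seq_len(K))

    alive_1y <- is.na(death_time) | death_time > 1
    recurrence_1y <- ifelse(
      alive_1y,
      stats::rbinom(n, 1, config$recurrence_prob_1y[as.character(arm)]),
      NA_integer_)

    cf <- config$cost_frailty
    fmult <- exp(cf * frailty - cf^2 / 2)
    comp <- config$cost_components
    qcols <- list()
    for (i in seq_len(nrow(comp))) {
      cl <- qty_col(comp$category[i], comp$period[i])
      if (is.null(qcols[[cl]])) qcols[[cl]] <- numeric(n)
      rows <- which(arm == comp$arm[i])
      if (is.na(comp$shape[i])) {
        q <- rep(comp$mean_qty[i], length(rows))
      } else {
        sh <- comp$shape[i]
        q <- stats::rgamma(length(rows), shape = sh,
                           scale = comp$mean_qty[i] / sh) * fmult[rows]
      }
      qcols[[cl]][rows] <- qcols[[cl]][rows] + q
    }
    # resource use in periods that start after death is structurally zero
    for (cl in names(qcols)) {
      period <- as.integer(sub(".*_p", "", cl))
      dead_before <- !is.na(death_time) & death_time <= (period - 1)
      qcols[[cl]][dead_before] <- 0
    }

    sh_a <- 1.2
    absence_days <- stats::rgamma(
      n, shape = sh_a,
      scale = config$absence_days_mean[as.character(arm)] / sh_a)

    out <- data.frame(
      id = seq_len(n), arm = arm, age = age, sex = sex,
      num_cords = num_cords, pem_score = pem_score,
      baseline_cost = baseline_cost, absence_days = absence_days,
      death_time = death_time, recurrence_1y = recurrence_1y,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(u), as.data.frame(qcols))
    attr(out, "followup_times") <- tt
    attr(out, "utility_floor") <- config$utility_floor
    class(out) <- c("trial_data", "data.frame")
    out
  })
}

#' Mask cells of a trial dataset under a missing-at-random mechanism
#'
#' Each patient's masking probability comes from the logistic model in the
#' [missingness_spec()] (covariate-dependent, hence recoverable by an
#' imputation model that conditions on those covariates). Masked cells become
#' `NA`, which is distinguishable from the structural zeros recorded at and
#' after death; death-censored zeros are never masked. Baseline utility and
#' intervention-delivery quantities are never masked.
#'
#' @param records A `trial_data` frame from [generate_trial()].
#' @param spec A [missingness_spec()].
#' @param seed Integer seed.
#' @return `records` with masked entries set to `NA`.
#' @export
apply_missingness <- function(records, spec = missingness_spec(), seed = 1L) {
  if (!inherits(spec, "missingness_spec")) {
    stop_field("spec", "must be a missingness_spec()")
  }
  tt <- attr(records, "followup_times")
  K <- length(tt)
  cf <- spec$coefficients
  co <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  lp <- co("intercept") +
    co("age_per_decade") * (records$age - 65) / 10 +
    co("sex_M") * (records$sex == "M") +
    co("arm_collagenase") * (records$arm == "collagenase") +
    co("baseline_utility") * (records$utility_1 - 0.8)
  p <- stats::plogis(lp)
  n <- nrow(records)
  dt <- records$death_time

  with_seed(seed, {
    if ("utilities" %in% spec$targets) {
      for (k in 2:K) {
        maskable <- is.na(dt) | tt[k] < dt   # structural zeros stay observed
        hit <- maskable & stats::runif(n) < p
        records[[paste0("utility_", k)]][hit] <- NA_real_
      }
    }
    if ("followup_costs" %in% spec$targets) {
      for (period in 1:2) {
        cols <- qty_col(FOLLOWUP_CATEGORIES, period)
        cols <- cols[cols %in% names(records)]
        if (length(cols) == 0) next
        maskable <- is.na(dt) | dt > (period - 1)
        hit <- maskable & stats::runif(n) < p
        for (cl in cols) records[[cl]][hit] <- NA_real_
      }
    }
    if ("pem_score" %in% spec$targets) {
      hit <- stats::runif(n) < p
      records$pem_score[hit] <- NA_real_
    }
    if ("recurrence_1y" %in% spec$targets) {
      maskable <- !is.na(records$recurrence_1y)
      hit <- maskable & stats::runif(n) < p
      records$recurrence_1y[hit] <- NA_integer_
    }
    records
  })
}

#' @rdname patient_table_io
#' @export
write_patient_table <- function(records, path) {
  tt <- attr(records, "followup_times")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# followup_times: %s",
                     paste(sprintf("%.17g", tt), collapse = ",")), con)
  out <- records
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  out[out == "NA"] <- NA
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and write patient tables as delimited text
#'
#' Tab-separated text with one row per patient; the follow-up schedule is
#' carried in a `# followup_times:` header comment. Numeric values are
#' written with 17 significant digits so the round trip is lossless.
#'
#' @param records A `trial_data` frame.
#' @param path File path.
#' @return `read_patient_table()` returns a `trial_data` frame;
#'   `write_patient_table()` returns `path` invisibly.
#' @name patient_table_io
#' @export
read_patient_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# followup_times:", first)) {
    stop_field("path", "missing '# followup_times:' header")
  }
  tt <- as.numeric(strsplit(sub("^# followup_times:\\s*", "", first), ",")[[1]])
  x <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                         stringsAsFactors = FALSE, na.strings = "NA")
  x$arm <- factor(x$arm, levels = ARM_LEVELS)
  for (cl in names(x)) {   # all-NA numeric columns read back as logical
    if (is.logical(x[[cl]])) x[[cl]] <- as.numeric(x[[cl]])
  }
  if ("recurrence_1y" %in% names(x)) {
    x$recurrence_1y <- as.integer(x$recurrence_1y)
  }
  attr(x, "followup_times") <- tt
  class(x) <- c("trial_data", "data.frame")
  x
}
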