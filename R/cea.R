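# Within-trial cost-effectiveness analysis: adjusted incremental cost/QALY
# estimation (SUR), nested nonparametric bootstrap across imputations,
# ICER with dominance labelling, net health benefit, cost-effectiveness
# acceptability curves and the vial-price threshold analysis.

#' Net health benefit
#'
#' NHB in QALY units: `delta_qaly - delta_cost / wtp`. Positive values mean
#' the intervention is cost-effective at the willingness-to-pay threshold.
#' This QALY-unit form is what published cost-effectiveness tables report to
#' three decimals; the monetary form is available as [nmb()].
#'
#' @param delta_cost Incremental cost in GBP (collagenase minus LF).
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay threshold in GBP per QALY (> 0); may be a
#'   vector.
#' @return NHB in QALYs, vectorised over the longest argument.
#' @examples
#' nhb(-1090, -0.003, 20000)   # 0.0515
#' @export
nhb <- function(delta_cost, delta_qaly, wtp) {
  if (any(!is.finite(wtp)) || any(wtp <= 0)) {
    stop_field("wtp", "must be a positive willingness-to-pay threshold")
  }
  delta_qaly - delta_cost / wtp
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`, i.e. [nhb()] scaled by the threshold.
#'
#' @inheritParams nhb
#' @return NMB in GBP.
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  if (any(!is.finite(wtp)) || any(wtp <= 0)) {
    stop_field("wtp", "must be a positive willingness-to-pay threshold")
  }
  wtp * delta_qaly - delta_cost
}

#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' Computes `delta_cost / delta_qaly` when the incremental QALYs are nonzero
#' and labels the cost-effectiveness plane quadrant: `"dominant"` (cheaper,
#' at least as effective), `"dominated"` (costlier, no more effective),
#' `"NE-quadrant"` (costlier and more effective: lower ratio favours the
#' intervention) or `"SW-quadrant"` (cheaper and less effective: a ratio
#' *above* the threshold favours the cheaper intervention). With zero
#' incremental QALYs only a label is returned.
#'
#' @inheritParams nhb
#' @return An `icer`: list with `ratio` (GBP/QALY or `NA`), `label`,
#'   `delta_cost`, `delta_qaly`.
#' @examples
#' icer(-1212, -0.048)   # SW quadrant, 25250 GBP per QALY
#' @export
icer <- function(delta_cost, delta_qaly) {
  label <- if (delta_qaly > 0) {
    if (delta_cost <= 0) "dominant" else "NE-quadrant"
  } else if (delta_qaly < 0) {
    if (delta_cost >= 0) "dominated" else "SW-quadrant"
  } else {
    if (delta_cost < 0) "dominant" else if (delta_cost > 0) "dominated"
    else "equivalent"
  }
  ratio <- if (delta_qaly != 0) delta_cost / delta_qaly else NA_real_
  structure(list(ratio = ratio, label = label, delta_cost = delta_cost,
                 delta_qaly = delta_qaly), class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  desc <- c("dominant" = "less costly, no less effective",
            "dominated" = "more costly, no more effective",
            "NE-quadrant" = "more costly and more effective",
            "SW-quadrant" = "less costly and less effective",
            "equivalent" = "equal costs and effects")[x$label]
  if (is.na(x$ratio)) {
    cat(sprintf("ICER: %s (%s); no ratio (zero incremental QALYs)\n",
                x$label, desc))
  } else {
    cat(sprintf("ICER: %s/QALY, %s (%s)\n", format_gbp(x$ratio), x$label, desc))
  }
  invisible(x)
}

# Decision rule equivalent to NHB > 0, expressed through the ICER quadrant.
icer_decision <- function(delta_cost, delta_qaly, wtp) {
  q <- icer(delta_cost, delta_qaly)
  switch(q$label,
         dominant = TRUE,
         dominated = FALSE,
         equivalent = FALSE,
         `NE-quadrant` = q$ratio < wtp,
         `SW-quadrant` = q$ratio > wtp)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of (incremental cost,
#' incremental QALY) draws with positive net benefit for the intervention.
#' Computed on the monetary scale (`wtp * dE - dC > 0`) so the curve is also
#' defined at `wtp = 0`, where it equals the probability of cost saving.
#'
#' @param delta_cost,delta_qaly Vectors of bootstrap or simulation draws.
#' @param lambdas Willingness-to-pay grid (GBP/QALY, >= 0).
#' @return Data frame with `lambda`, `p_ce` (intervention) and
#'   `p_comparator` (`1 - p_ce` up to ties at exactly zero net benefit).
#' @export
ceac_curve <- function(delta_cost, delta_qaly, lambdas = seq(0, 50000, 500)) {
  if (length(delta_cost) == 0) stop("empty draw set", call. = FALSE)
  check_nonneg(lambdas, "lambdas")
  p <- vapply(lambdas, function(l) mean(l * delta_qaly - delta_cost > 0),
              numeric(1))
  pc <- vapply(lambdas, function(l) mean(l * delta_qaly - delta_cost < 0),
               numeric(1))
  data.frame(lambda = lambdas, p_ce = p, p_comparator = pc)
}

#' Bootstrap configuration for the within-trial CEA
#'
#' @param reps_per_imputation Patient-level resamples per imputed dataset
#'   (default 200; with the default 25 imputations this gives the
#'   conventional 5000 total draws).
#' @param lambdas Willingness-to-pay grid for acceptability curves.
#' @param seed Integer seed.
#' @return A `bootstrap_config`.
#' @export
bootstrap_config <- function(reps_per_imputation = 200,
                             lambdas = seq(0, 50000, 500), seed = 1L) {
  check_count(reps_per_imputation, "reps_per_imputation", min = 1)
  structure(list(reps_per_imputation = reps_per_imputation,
                 lambdas = lambdas, seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Nonparametric bootstrap of the SUR incremental estimates
#'
#' For each completed (imputed) dataset, draws patient-level resamples
#' stratified by arm and refits the SUR system, pooling all
#' `m * reps_per_imputation` draws into one distribution of
#' (incremental cost, incremental QALYs). Resamples on which the design is
#' singular (e.g. a baseline covariate resampled to a constant) are redrawn
#' and counted.
#'
#' @param datasets List of completed analysis frames, each with columns
#'   `cost`, `qaly`, `arm`, `baseline_cost`, `baseline_utility`.
#' @param config A [bootstrap_config()].
#' @return A `cea_boot` data frame with columns `imp`, `rep`, `delta_cost`,
#'   `delta_qaly`; attribute `redraws` counts rejected resamples.
#' @export
bootstrap_cea <- function(datasets, config = bootstrap_config()) {
  if (!is.list(datasets) || length(datasets) == 0) {
    stop_field("datasets", "must be a non-empty list of completed datasets")
  }
  reps <- config$reps_per_imputation
  redraws <- 0L
  out <- with_seed(config$seed, {
    res <- vector("list", length(datasets))
    for (j in seq_along(datasets)) {
      d <- datasets[[j]]
      X <- stats::model.matrix(~ arm + baseline_cost + baseline_utility, d)
      arm_idx <- grep("^arm", colnames(X))
      idx_lf <- which(d$arm == "LF")
      idx_co <- which(d$arm == "collagenase")
      if (length(idx_lf) == 0 || length(idx_co) == 0) {
        stop("both arms must be present in every dataset", call. = FALSE)
      }
      dc <- de <- numeric(reps)
      for (r in seq_len(reps)) {
        repeat {
          idx <- c(sample(idx_lf, replace = TRUE),
                   sample(idx_co, replace = TRUE))
          fit <- tryCatch(
            sur_fgls(X[idx, , drop = FALSE], d$cost[idx], d$qaly[idx]),
            error = function(e) NULL)
          if (!is.null(fit)) break
          redraws <- redraws + 1L
        }
        dc[r] <- fit$b1[arm_idx]
        de[r] <- fit$b2[arm_idx]
      }
      res[[j]] <- data.frame(imp = j, rep = seq_len(reps),
                             delta_cost = dc, delta_qaly = de)
    }
    do.call(rbind, res)
  })
  attr(out, "redraws") <- redraws
  attr(out, "lambdas") <- config$lambdas
  class(out) <- c("cea_boot", "data.frame")
  out
}

# Completed analysis frame -> outcome columns at a horizon: `cost` (scenario
# total over the horizon) and `qaly` (AUC to the horizon).
finalize_horizon <- function(adf, horizon) {
  tt <- attr(adf, "followup_times")
  scenario <- attr(adf, "scenario")
  cost <- adf$intervention_cost + adf$followup_cost_p1
  if (horizon >= 2) cost <- cost + adf$followup_cost_p2
  if (!is.null(scenario) && scenario$perspective == "societal") {
    cost <- cost + adf$societal_cost
  }
  K <- length(tt)
  u <- cbind(adf$baseline_utility,
             as.matrix(adf[paste0("utility_", 2:K)]))
  qaly <- vapply(seq_len(nrow(adf)), function(i) {
    auc_qalys(u[i, ], tt, horizon, death_time = adf$death_time[i])
  }, numeric(1))
  adf$cost <- cost
  adf$qaly <- qaly
  adf
}

#' Maximum vial price at which the injection stays cost-effective
#'
#' Re-costs the collagenase drug line at each candidate vial price, refits
#' the SUR system on every imputed dataset, Rubin-pools the incremental
#' estimates and reports the largest price on the grid with pooled net health
#' benefit >= 0 at the given threshold. Net benefit is strictly decreasing in
#' price (every extra pound of vial price adds at least a pound per treated
#' collagenase patient), so the search is monotone.
#'
#' @param datasets List of completed analysis frames (see
#'   [finalize_horizon()] callers); each must carry `qty_vial`, `cost`,
#'   `qaly` and the SUR covariates.
#' @param base_price Vial price already embedded in `cost` (GBP).
#' @param lambda Willingness-to-pay threshold (GBP/QALY).
#' @param price_grid Increasing grid of candidate vial prices (GBP).
#' @return List with `threshold` (largest acceptable price, or `NA` if the
#'   net benefit is negative over the whole grid, with `status =
#'   "below_grid"`), and `grid` (price vs pooled NHB).
#' @export
price_threshold <- function(datasets, base_price, lambda,
                            price_grid = seq(0, 2000, 10)) {
  if (any(diff(price_grid) <= 0)) {
    stop_field("price_grid", "must be strictly increasing")
  }
  nhb_at <- function(price) {
    est_c <- est_q <- var_c <- var_q <- numeric(length(datasets))
    for (j in seq_along(datasets)) {
      d <- datasets[[j]]
      d$cost <- d$cost + d$qty_vial * (price - base_price)
      fit <- fit_sur(d)
      est_c[j] <- fit$delta["delta_cost"]
      est_q[j] <- fit$delta["delta_qaly"]
      var_c[j] <- fit$delta_vcov[1, 1]
      var_q[j] <- fit$delta_vcov[2, 2]
    }
    if (length(datasets) >= 2) {
      dc <- rubin_pool(est_c, var_c)$estimate
      dq <- rubin_pool(est_q, var_q)$estimate
    } else {
      dc <- est_c
      dq <- est_q
    }
    nhb(dc, dq, lambda)
  }
  vals <- vapply(price_grid, nhb_at, numeric(1))
  ok <- which(vals >= 0)
  list(threshold = if (length(ok)) price_grid[max(ok)] else NA_real_,
       status = if (length(ok)) "within_grid" else "below_grid",
       lambda = lambda,
       grid = data.frame(price = price_grid, nhb = vals))
}

#' Fit the within-trial cost-effectiveness analysis
#'
#' The main within-trial fitting function. Assembles the analysis table
#' under a costing scenario, handles missing data (chained-equation multiple
#' imputation by default, or listwise deletion for the complete-case
#' sensitivity analysis), estimates adjusted incremental costs and QALYs by
#' seemingly unrelated regression on each completed dataset, pools by
#' Rubin's rules, bootstraps patients within each imputation for percentile
#' confidence intervals and acceptability curves, and evaluates ICER, NHB
#' and the probability of cost-effectiveness at the chosen thresholds, per
#' analysis horizon.
#'
#' @param data A `trial_data` frame (may contain missing cells).
#' @param units A `unit_cost_table`.
#' @param scenario A [costing_scenario()].
#' @param horizons Analysis horizons in years (each must be a follow-up
#'   time; default 1 and 2).
#' @param mi An [mi_config()], or `NULL` together with
#'   `complete_case = TRUE`.
#' @param boot A [bootstrap_config()].
#' @param lambdas Thresholds at which NHB and the probability of
#'   cost-effectiveness are reported (GBP/QALY).
#' @param complete_case Use listwise deletion instead of imputation.
#' @param seed Master seed (propagated to imputation and bootstrap).
#' @return A `cea_fit`; see [print.cea_fit()], [coef.cea_fit()],
#'   [confint.cea_fit()], [summary.cea_fit()], [plot.cea_fit()].
#' @examples
#' dat <- generate_trial(trial_config(n_per_arm = 50, seed = 3))
#' fit <- cea_trial(dat, mi = mi_config(m = 2, iterations = 2),
#'                  boot = bootstrap_config(reps_per_imputation = 20),
#'                  horizons = 1)
#' coef(fit)
#' @export
cea_trial <- function(data, units = default_unit_costs(),
                      scenario = costing_scenario(),
                      horizons = c(1, 2), mi = mi_config(),
                      boot = bootstrap_config(),
                      lambdas = c(20000, 30000),
                      complete_case = FALSE, seed = 1L) {
  adf <- assemble_cea_data(data, units, scenario)
  tt <- attr(adf, "followup_times")
  if (complete_case) {
    keep_cols <- c(grep("^utility_", names(adf), value = TRUE),
                   "followup_cost_p1", "followup_cost_p2",
                   "baseline_cost", "baseline_utility")
    cc <- stats::complete.cases(adf[keep_cols])
    stacks <- list(adf[cc, , drop = FALSE])
    for (a in names(attributes(adf))) {
      if (!a %in% c("names", "row.names", "class")) {
        attr(stacks[[1]], a) <- attr(adf, a)
      }
    }
    n_analysis <- sum(cc)
  } else {
    mi$seed <- as.integer(seed)
    stack <- mice_impute(adf, mi)
    stacks <- stack$imputations
    n_analysis <- nrow(adf)
  }
  results <- list()
  for (h in horizons) {
    frames <- lapply(stacks, finalize_horizon, horizon = h)
    m <- length(frames)
    est <- matrix(NA_real_, m, 2)
    vv <- matrix(NA_real_, m, 2)
    for (j in seq_len(m)) {
      fit <- fit_sur(frames[[j]])
      est[j, ] <- fit$delta
      vv[j, ] <- diag(fit$delta_vcov)
    }
    if (m >= 2) {
      pc <- rubin_pool(est[, 1], vv[, 1])
      pq <- rubin_pool(est[, 2], vv[, 2])
      dc <- pc$estimate; dq <- pq$estimate
      se <- c(pc$se, pq$se)
    } else {
      dc <- est[1, 1]; dq <- est[1, 2]
      se <- sqrt(vv[1, ])
    }
    bconf <- boot
    bconf$seed <- as.integer(seed + 7919 * which(horizons == h)[1])
    bdraws <- bootstrap_cea(frames, bconf)
    ci_cost <- stats::quantile(bdraws$delta_cost, c(0.025, 0.975), names = FALSE)
    ci_qaly <- stats::quantile(bdraws$delta_qaly, c(0.025, 0.975), names = FALSE)
    curve <- ceac_curve(bdraws$delta_cost, bdraws$delta_qaly, boot$lambdas)
    p_ce <- vapply(lambdas, function(l) {
      mean(l * bdraws$delta_qaly - bdraws$delta_cost > 0)
    }, numeric(1))
    arm_means <- vapply(ARM_LEVELS, function(a) {
      cm <- rowMeans(vapply(frames, function(f) {
        c(mean(f$cost[f$arm == a]), mean(f$qaly[f$arm == a]),
          mean(f$intervention_cost[f$arm == a]))
      }, numeric(3)))
      cm
    }, numeric(3))
    dimnames(arm_means) <- list(c("cost", "qaly", "intervention_cost"),
                                ARM_LEVELS)
    results[[as.character(h)]] <- list(
      horizon = h, delta_cost = dc, delta_qaly = dq, se = se,
      ci_cost = ci_cost, ci_qaly = ci_qaly,
      icer = icer(dc, dq),
      nhb = stats::setNames(nhb(dc, dq, lambdas), lambdas),
      p_ce = stats::setNames(p_ce, lambdas),
      ceac = curve, boot = bdraws, per_imputation = est,
      arm_means = arm_means)
  }
  structure(list(results = results, horizons = horizons, lambdas = lambdas,
                 scenario = scenario, n = n_analysis,
                 m = length(stacks), complete_case = complete_case,
                 stacks = stacks, seed = seed, call = match.call()),
            class = "cea_fit")
}

#' @describeIn cea_trial Print a compact per-horizon results table.
#' @param x,object A `cea_fit`.
#' @param ... Unused.
#' @export
print.cea_fit <- function(x, ...) {
  cat(sprintf(
    "Within-trial cost-effectiveness analysis (%s, %s)\n n = %d patients, %s\n",
    x$scenario$method,
    x$scenario$perspective,
    x$n,
    if (x$complete_case) "complete cases" else
      sprintf("%d imputations", x$m)))
  for (res in x$results) {
    cat(sprintf("\n%g-year results\n", res$horizon))
    cat(sprintf("  Incremental cost  %s (95%% CI %s to %s)\n",
                format_gbp(res$delta_cost), format_gbp(res$ci_cost[1]),
                format_gbp(res$ci_cost[2])))
    cat(sprintf("  Incremental QALYs %s (95%% CI %s to %s)\n",
                format_qaly(res$delta_qaly), format_qaly(res$ci_qaly[1]),
                format_qaly(res$ci_qaly[2])))
    lbl <- res$icer$label
    cat(sprintf("  ICER              %s\n",
                if (is.na(res$icer$ratio)) lbl else
                  sprintf("%s/QALY (%s)", format_gbp(res$icer$ratio), lbl)))
    for (l in names(res$nhb)) {
      cat(sprintf("  NHB at %s/QALY: %s;  P(cost-effective) %s\n",
                  format_gbp(as.numeric(l)), format_qaly(res$nhb[[l]]),
                  format_pct(res$p_ce[[l]])))
    }
  }
  invisible(x)
}

#' @describeIn cea_trial Incremental cost and QALYs per horizon.
#' @export
coef.cea_fit <- function(object, ...) {
  t(vapply(object$results, function(r) {
    c(delta_cost = r$delta_cost, delta_qaly = r$delta_qaly)
  }, numeric(2)))
}

#' @describeIn cea_trial 95 percent percentile bootstrap intervals.
#' @param parm,level Standard `confint` arguments (only `level = 0.95`
#'   bootstrap percentiles are stored).
#' @export
confint.cea_fit <- function(object, parm, level = 0.95, ...) {
  out <- do.call(rbind, lapply(object$results, function(r) {
    rbind(r$ci_cost, r$ci_qaly)
  }))
  rownames(out) <- as.vector(t(outer(
    names(object$results), c(": delta_cost", ": delta_qaly"), paste0)))
  colnames(out) <- c("2.5 %", "97.5 %")
  out
}

#' @describeIn cea_trial Full summary, including per-imputation spread.
#' @export
summary.cea_fit <- function(object, ...) {
  print(object)
  for (res in object$results) {
    cat(sprintf("\n%g-year per-arm means (pooled): cost %s / %s, QALY %s / %s\n",
                res$horizon,
                format_gbp(res$arm_means["cost", "LF"]),
                format_gbp(res$arm_means["cost", "collagenase"]),
                format_qaly(res$arm_means["qaly", "LF"]),
                format_qaly(res$arm_means["qaly", "collagenase"])))
  }
  invisible(object)
}

#' @describeIn cea_trial Plot acceptability curves per horizon.
#' @export
plot.cea_fit <- function(x, ...) {
  graphics::plot(NULL, xlim = range(x$results[[1]]$ceac$lambda),
                 ylim = c(0, 1), xlab = "Willingness to pay (GBP/QALY)",
                 ylab = "P(collagenase cost-effective)",
                 main = "Cost-effectiveness acceptability")
  cols <- grDevices::hcl.colors(max(2, length(x$results)), "Dark 2")
  for (i in seq_along(x$results)) {
    graphics::lines(x$results[[i]]$ceac$lambda, x$results[[i]]$ceac$p_ce,
                    col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = paste0(x$horizons, "-year"),
                   col = cols[seq_along(x$results)], lwd = 2, bty = "n")
  invisible(x)
}
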