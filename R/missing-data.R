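# Multiple imputation by chained equations over follow-up utilities and
# category-level costs, with Rubin-rules pooling of downstream estimates.
# Deceased patients' structural zeros (utilities and costs after death) are
# never imputed and never used to fit the imputation models.

#' Assemble the analysis table for the within-trial CEA
#'
#' Joins the patient table with its scenario costs into the per-patient
#' analysis frame the CEA operates on: arm, demographics, baseline cost and
#' utility, post-baseline utilities, bucketed costs (intervention, follow-up
#' per year, societal), vial count (for the price-threshold analysis), death
#' time, trial status and one-year recurrence. Missing quantities/utilities
#' propagate as `NA`; impute with [mice_impute()].
#'
#' @param data A `trial_data` frame.
#' @param units A `unit_cost_table`.
#' @param scenario A [costing_scenario()].
#' @return A `cea_data` frame with attribute `followup_times`.
#' @export
assemble_cea_data <- function(data, units = default_unit_costs(),
                              scenario = costing_scenario()) {
  tt <- attr(data, "followup_times")
  if (is.null(tt)) stop_field("data", "missing followup_times attribute")
  costs <- cost_trial(data, units, scenario)
  out <- data.frame(
    id = data$id, arm = as_arm(data$arm), age = data$age, sex = data$sex,
    num_cords = data$num_cords, pem_score = data$pem_score,
    baseline_cost = data$baseline_cost,
    baseline_utility = data$utility_1,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(tt)[-1]) out[[paste0("utility_", k)]] <- data[[paste0("utility_", k)]]
  out$intervention_cost <- costs$intervention_cost
  out$followup_cost_p1 <- costs$followup_cost_p1
  out$followup_cost_p2 <- costs$followup_cost_p2
  out$societal_cost <- costs$societal_cost
  out$qty_vial <- if ("qty_vial_p1" %in% names(data)) data$qty_vial_p1 else 0
  out$death_time <- data$death_time
  out$status <- factor(ifelse(is.na(data$death_time), "ongoing", "deceased"),
                       levels = c("ongoing", "deceased"))
  out$recurrence_1y <- as.numeric(data$recurrence_1y)
  attr(out, "followup_times") <- tt
  attr(out, "scenario") <- scenario
  class(out) <- c("cea_data", "data.frame")
  out
}

#' Multiple-imputation configuration
#'
#' @param m Number of imputations (>= 2; default 25).
#' @param iterations Chained-equation sweeps per imputation (default 10).
#' @param method Optional named character vector overriding the per-variable
#'   method (`"linear"`, `"pmm"`, `"logistic"`). By default continuous
#'   variables use predictive mean matching (which respects skewness and
#'   scale bounds) and binary variables logistic regression.
#' @param predictors Covariates entering every conditional model in addition
#'   to the other imputed variables. Defaults to treatment allocation, age,
#'   sex, number of cords, baseline cost and utility, and trial status.
#' @param donors Number of nearest donors for predictive mean matching.
#' @param seed Integer seed for the whole MI run.
#' @return An `mi_config`.
#' @export
mi_config <- function(m = 25, iterations = 10, method = NULL,
                      predictors = c("arm", "age", "sex", "num_cords",
                                     "baseline_cost", "baseline_utility",
                                     "status"),
                      donors = 5, seed = 1L) {
  check_count(m, "m", min = 2)
  check_count(iterations, "iterations", min = 1)
  check_count(donors, "donors", min = 1)
  if (!is.null(method) &&
      !all(method %in% c("linear", "pmm", "logistic"))) {
    stop_field("method", "entries must be 'linear', 'pmm' or 'logistic'")
  }
  structure(list(m = m, iterations = iterations, method = method,
                 predictors = predictors, donors = donors,
                 seed = as.integer(seed)),
            class = "mi_config")
}

# Structural-zero mask: TRUE where a cell is a death-censored zero that must
# neither be imputed nor used to fit imputation models.
structural_mask <- function(data, var) {
  tt <- attr(data, "followup_times")
  dt <- data$death_time
  if (grepl("^utility_", var)) {
    k <- as.integer(sub("^utility_", "", var))
    return(!is.na(dt) & tt[k] >= dt)
  }
  if (var == "followup_cost_p2") return(!is.na(dt) & dt <= 1)
  if (var == "recurrence_1y") return(!is.na(dt) & dt <= 1)
  rep(FALSE, nrow(data))
}

# One Bayesian-draw linear model step: returns the fitted object pieces needed
# by the "linear" and "pmm" methods.
bayes_lm_draw <- function(X, y) {
  qrx <- qr(X)
  rank <- qrx$rank
  keep <- qrx$pivot[seq_len(rank)]
  Xk <- X[, keep, drop = FALSE]
  XtX <- crossprod(Xk)
  R <- chol(XtX + diag(1e-10, ncol(Xk)))
  beta <- backsolve(R, forwardsolve(t(R), crossprod(Xk, y)))
  resid <- y - Xk %*% beta
  df <- max(length(y) - rank, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  V <- chol2inv(R)
  beta_star <- beta + t(chol(V + diag(1e-12, ncol(V)))) %*%
    stats::rnorm(ncol(Xk)) * sqrt(sigma2)
  list(keep = keep, beta = beta, beta_star = beta_star, sigma2 = sigma2)
}

impute_var_once <- function(data, var, method, pred_cols, donors, struct) {
  miss <- is.na(data[[var]]) & !struct
  obs <- !is.na(data[[var]]) & !struct
  if (!any(miss)) return(data)
  # factors collapsed to a single observed level carry no information and
  # would break model.matrix
  pred_cols <- pred_cols[vapply(pred_cols, function(p) {
    length(unique(data[[p]][!is.na(data[[p]])])) > 1
  }, logical(1))]
  if (length(pred_cols) == 0) pred_cols <- NULL
  form <- if (is.null(pred_cols)) ~1 else stats::reformulate(pred_cols)
  X <- stats::model.matrix(form, data = data)
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[miss, , drop = FALSE]
  y <- data[[var]][obs]
  if (method == "logistic") {
    fit <- suppressWarnings(stats::glm.fit(Xo, y,
                                           family = stats::binomial()))
    ok <- !is.na(fit$coefficients)
    V <- chol2inv(chol(crossprod(Xo[, ok, drop = FALSE] *
                                   sqrt(fit$weights)) + diag(1e-8, sum(ok))))
    b_star <- fit$coefficients[ok] + t(chol(V)) %*% stats::rnorm(sum(ok))
    p <- stats::plogis(drop(Xm[, ok, drop = FALSE] %*% b_star))
    data[[var]][miss] <- stats::rbinom(sum(miss), 1, p)
  } else {
    d <- bayes_lm_draw(Xo, y)
    if (method == "linear") {
      data[[var]][miss] <- drop(Xm[, d$keep, drop = FALSE] %*% d$beta_star) +
        stats::rnorm(sum(miss)) * sqrt(d$sigma2)
    } else { # pmm, type-1 matching
      yhat_obs <- drop(Xo[, d$keep, drop = FALSE] %*% d$beta)
      yhat_mis <- drop(Xm[, d$keep, drop = FALSE] %*% d$beta_star)
      nd <- min(donors, length(y))
      for (i in seq_along(yhat_mis)) {
        dist <- abs(yhat_obs - yhat_mis[i])
        cand <- order(dist)[seq_len(nd)]
        data[[var]][which(miss)[i]] <- y[sample(cand, 1)]
      }
    }
  }
  data
}

#' Multiple imputation by chained equations
#'
#' Creates `m` completed copies of a [assemble_cea_data()] frame. Variables
#' with missing cells (post-baseline utilities, per-year follow-up costs,
#' hand-outcome score, one-year recurrence) are imputed by iterated
#' conditional draws, visiting variables in order of increasing missingness.
#' Observed cells are never altered; structural zeros recorded after death
#' are preserved as zeros, excluded from model fitting and never imputed.
#'
#' @param data A `cea_data` frame (may contain `NA`s).
#' @param config An [mi_config()].
#' @return An `mi_stack`: list with elements `imputations` (list of `m`
#'   completed frames), `m`, and `config`.
#' @export
mice_impute <- function(data, config = mi_config()) {
  if (!inherits(config, "mi_config")) stop_field("config", "must be mi_config()")
  cand <- c(grep("^utility_[0-9]+$", names(data), value = TRUE),
            "followup_cost_p1", "followup_cost_p2", "pem_score",
            "recurrence_1y")
  cand <- cand[cand %in% names(data)]
  struct <- lapply(cand, function(v) structural_mask(data, v))
  names(struct) <- cand
  fmiss <- vapply(cand, function(v) {
    mean(is.na(data[[v]][!struct[[v]]]))
  }, numeric(1))
  fully_missing <- cand[is.nan(fmiss) | fmiss >= 1]
  if (length(fully_missing) > 0) {
    stop(sprintf("variable(s) with no observed values cannot be imputed: %s",
                 paste(fully_missing, collapse = ", ")), call. = FALSE)
  }
  # structural (death-censored) cells are fixed at zero: never imputed, never
  # fed to the conditional models as missing, usable as predictors
  for (v in cand) data[[v]][struct[[v]]] <- 0
  vars <- cand[fmiss > 0]
  vars <- vars[order(fmiss[match(vars, cand)])]     # increasing missingness
  if (length(vars) == 0) {
    out <- list(imputations = rep(list(data), config$m), m = config$m,
                config = config)
    class(out) <- "mi_stack"
    return(out)
  }
  method_for <- function(v) {
    if (!is.null(config$method) && v %in% names(config$method)) {
      return(config$method[[v]])
    }
    if (v == "recurrence_1y") "logistic" else "pmm"
  }
  imputations <- with_seed(config$seed, {
    lapply(seq_len(config$m), function(j) {
      d <- data
      # initial fill: random draws from the observed margin
      for (v in vars) {
        miss <- is.na(d[[v]]) & !struct[[v]]
        obsv <- d[[v]][!is.na(d[[v]]) & !struct[[v]]]
        d[[v]][miss] <- sample(obsv, sum(miss), replace = TRUE)
      }
      for (sweep in seq_len(config$iterations)) {
        for (v in vars) {
          preds <- c(setdiff(config$predictors, v), setdiff(vars, v))
          d2 <- d
          d2[[v]] <- data[[v]]          # restore NAs for the working variable
          d <- impute_var_once(d2, v, method_for(v), preds, config$donors,
                               struct[[v]])
        }
      }
      d
    })
  })
  out <- list(imputations = imputations, m = config$m, config = config,
              imputed_vars = vars)
  class(out) <- "mi_stack"
  out
}

#' @export
print.mi_stack <- function(x, ...) {
  cat(sprintf("Multiple imputation stack: m = %d completed datasets (%d rows)\n",
              x$m, nrow(x$imputations[[1]])))
  if (length(x$imputed_vars %||% character()) > 0) {
    cat("Imputed variables:", paste(x$imputed_vars, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write or read an imputation stack as one delimited table
#'
#' The `m` completed datasets are stacked with an `.imp` index column.
#'
#' @param stack An `mi_stack`.
#' @param path File path.
#' @name mi_stack_io
#' @export
write_mi_stack <- function(stack, path) {
  tabs <- lapply(seq_len(stack$m), function(j) {
    cbind(.imp = j, as.data.frame(stack$imputations[[j]]))
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mi_stack_io
#' @export
read_mi_stack <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  imps <- split(x[setdiff(names(x), ".imp")], x$.imp)
  out <- list(imputations = unname(imps), m = length(imps), config = NULL)
  class(out) <- "mi_stack"
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates Point estimate from each of `m >= 2` imputations.
#' @param variances Squared standard error from each imputation.
#' @return List with `estimate` (mean of estimates), `within`, `between`,
#'   `variance` (within + (1 + 1/m) between), `se`, and `df` (the standard
#'   small-sample degrees of freedom; `Inf` when the between-imputation
#'   variance is zero).
#' @examples
#' rubin_pool(c(1, 3), c(1, 1))  # estimate 2, total variance 4
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) {
    stop_field("estimates", "need m >= 2 estimates with matching variances")
  }
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  df <- if (b <= 0) Inf else (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
  list(estimate = qbar, within = w, between = b, variance = total,
       se = sqrt(total), df = df)
}

#' Report associations between missingness and candidate predictors
#'
#' Diagnostic screening only (it does not alter the imputation model):
#' for each variable with missing cells, logistic regressions of the
#' missingness indicator on each continuous/binary candidate and chi-square
#' tests for categorical candidates.
#'
#' @param data A `cea_data` frame.
#' @param candidates Candidate predictor columns.
#' @return Data frame with variable, candidate, test and p-value.
#' @export
missingness_screen <- function(data,
                               candidates = c("arm", "age", "sex",
                                              "num_cords", "baseline_cost",
                                              "baseline_utility")) {
  vars <- names(data)[vapply(data, anyNA, logical(1))]
  vars <- setdiff(vars, c("death_time"))
  rows <- list()
  for (v in vars) {
    miss <- as.integer(is.na(data[[v]]) & !structural_mask(data, v))
    for (cc in candidates) {
      x <- data[[cc]]
      if (is.numeric(x)) {
        fit <- suppressWarnings(stats::glm(miss ~ x, family = stats::binomial()))
        p <- summary(fit)$coefficients
        pv <- if (nrow(p) > 1) p[2, 4] else NA_real_
        test <- "logistic"
      } else {
        tab <- table(x, miss)
        pv <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                       error = function(e) NA_real_)
        test <- "chi-square"
      }
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, candidate = cc, test = test, p_value = pv)
    }
  }
  do.call(rbind, rows) %||% data.frame(variable = character(),
                                       candidate = character(),
                                       test = character(),
                                       p_value = numeric())
}
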