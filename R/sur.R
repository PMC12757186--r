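# Seemingly unrelated regression for the two-equation (cost, QALY) system:
# equation-by-equation OLS, residual covariance, then one feasible GLS step.
# With identical regressors in both equations the FGLS estimator equals OLS
# exactly; that algebraic identity is the estimator's test oracle.

# Core FGLS on prebuilt design matrices. X2 = NULL means both equations share
# X1. Returns stacked coefficients (cost first), their covariance, and the
# residual covariance of the two equations.
sur_fgls <- function(X1, y1, y2, X2 = NULL) {
  same <- is.null(X2)
  if (same) X2 <- X1
  n <- nrow(X1)
  q1 <- qr(X1)
  q2 <- if (same) q1 else qr(X2)
  if (q1$rank < ncol(X1) || q2$rank < ncol(X2)) {
    stop("singular design matrix in SUR fit", call. = FALSE)
  }
  b1 <- qr.coef(q1, y1)
  b2 <- qr.coef(q2, y2)
  e1 <- y1 - X1 %*% b1
  e2 <- y2 - X2 %*% b2
  S <- crossprod(cbind(e1, e2)) / n
  # degenerate (noiseless) residual covariance: GLS weighting is undefined,
  # and OLS is already exact
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <
      1e-12 * max(abs(S), 1e-300)) {
    k1 <- ncol(X1)
    vc <- matrix(0, k1 + ncol(X2), k1 + ncol(X2))
    vc[seq_len(k1), seq_len(k1)] <- S[1, 1] * chol2inv(qr.R(q1))
    vc[-seq_len(k1), -seq_len(k1)] <- S[2, 2] * chol2inv(qr.R(q2))
    return(list(b1 = drop(b1), b2 = drop(b2), vcov = vc, sigma = S, n = n))
  }
  Si <- solve(S)
  A11 <- Si[1, 1] * crossprod(X1)
  A12 <- Si[1, 2] * crossprod(X1, X2)
  A22 <- Si[2, 2] * crossprod(X2)
  lhs <- rbind(cbind(A11, A12), cbind(t(A12), A22))
  rhs <- c(Si[1, 1] * crossprod(X1, y1) + Si[1, 2] * crossprod(X1, y2),
           Si[1, 2] * crossprod(X2, y1) + Si[2, 2] * crossprod(X2, y2))
  vc <- solve(lhs)
  b <- drop(vc %*% rhs)
  k1 <- ncol(X1)
  list(b1 = b[seq_len(k1)], b2 = b[-seq_len(k1)], vcov = vc, sigma = S, n = n)
}

#' Seemingly unrelated regression of cost and QALY on treatment
#'
#' Jointly estimates the incremental-cost and incremental-QALY equations with
#' cross-equation error correlation (one feasible-GLS step after OLS). Both
#' equations regress on treatment arm plus baseline cost and baseline utility
#' by default, the standard within-trial adjustment set; with a common
#' regressor set the SUR coefficients coincide exactly with per-equation
#' least squares, but their covariance matrix carries the cross-equation
#' correlation used by net-benefit inference.
#'
#' @param data Data frame with the outcome and covariate columns.
#' @param cost_var,effect_var Outcome column names (default `"cost"`,
#'   `"qaly"`).
#' @param covariates Shared regressor names (default `arm`, `baseline_cost`,
#'   `baseline_utility`). `arm` must be a factor with levels LF, collagenase.
#' @return A `sur_fit` with elements `coefficients` (matrix, one column per
#'   equation), `vcov`, `sigma` (2x2 residual covariance), `delta`
#'   (named vector: `delta_cost`, `delta_qaly`, the treatment coefficients,
#'   collagenase minus LF), `delta_vcov`, and `n`.
#' @examples
#' d <- data.frame(arm = factor(rep(c("LF", "collagenase"), each = 40),
#'                              levels = c("LF", "collagenase")),
#'                 baseline_cost = rexp(80, 1/100),
#'                 baseline_utility = runif(80, 0.6, 1))
#' d$cost <- 2000 - 1100 * (d$arm == "collagenase") + rnorm(80, 0, 50)
#' d$qaly <- 0.8 - 0.003 * (d$arm == "collagenase") + rnorm(80, 0, 0.01)
#' fit_sur(d)$delta
#' @export
fit_sur <- function(data, cost_var = "cost", effect_var = "qaly",
                    covariates = c("arm", "baseline_cost",
                                   "baseline_utility")) {
  X <- stats::model.matrix(stats::reformulate(covariates), data = data)
  y1 <- data[[cost_var]]
  y2 <- data[[effect_var]]
  if (anyNA(y1) || anyNA(y2) || anyNA(X)) {
    stop("missing values in SUR inputs: impute or use complete cases first",
         call. = FALSE)
  }
  fit <- sur_fgls(X, y1, y2)
  arm_idx <- grep("^arm", colnames(X))
  if (length(arm_idx) != 1) {
    stop_field("covariates", "must include a two-level `arm` factor")
  }
  k <- ncol(X)
  co <- cbind(cost = fit$b1, effect = fit$b2)
  rownames(co) <- colnames(X)
  delta <- c(delta_cost = unname(fit$b1[arm_idx]),
             delta_qaly = unname(fit$b2[arm_idx]))
  dv <- fit$vcov[c(arm_idx, k + arm_idx), c(arm_idx, k + arm_idx)]
  dimnames(dv) <- list(names(delta), names(delta))
  structure(list(coefficients = co, vcov = fit$vcov, sigma = fit$sigma,
                 delta = delta, delta_vcov = dv, n = fit$n,
                 covariates = covariates),
            class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, ...) {
  cat("Seemingly unrelated regression (cost, QALY), n =", x$n, "\n")
  print(round(x$coefficients, 6))
  cat(sprintf("\nIncremental (collagenase - LF): cost %.2f GBP, QALY %.5f\n",
              x$delta["delta_cost"], x$delta["delta_qaly"]))
  cat(sprintf("Residual correlation: %.3f\n",
              stats::cov2cor(x$sigma)[1, 2]))
  invisible(x)
}

#' @export
coef.sur_fit <- function(object, ...) object$coefficients

#' @export
vcov.sur_fit <- function(object, ...) object$vcov
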