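# Health outcomes: area-under-the-curve QALYs from utility trajectories, and
# the pluggable descriptive-profile-to-utility value set.

#' Area-under-the-curve QALYs from a utility trajectory
#'
#' Trapezoidal integral of the piecewise-linear utility curve through the
#' scheduled follow-up utilities, from time 0 to `horizon`. If the patient
#' dies before the horizon, utility is interpolated linearly from the last
#' pre-death observation down to 0 at `death_time` and is exactly 0
#' thereafter (a stricter convention than only zeroing the scheduled
#' follow-ups after death).
#'
#' @param utilities Utility at each follow-up time (no missing values:
#'   trajectories must be completed by imputation first).
#' @param times Follow-up times in years, strictly increasing, starting at 0.
#' @param horizon Analysis horizon in years; must be one of `times`.
#' @param death_time Death time in years, or `NA`/`NULL` if alive.
#' @param floor Lower bound of the utility scale (validation only).
#' @return QALYs accrued over `[0, horizon]`.
#' @examples
#' auc_qalys(c(0.8, 0.6), c(0, 1), horizon = 1)          # 0.7
#' auc_qalys(c(0.8, 0), c(0, 1), horizon = 1, death_time = 0.5)  # 0.2
#' @export
auc_qalys <- function(utilities, times, horizon, death_time = NULL,
                      floor = UTILITY_FLOOR) {
  if (length(utilities) != length(times)) {
    stop_field("utilities", "must have one value per follow-up time")
  }
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop_field("times", "must be strictly increasing and start at 0")
  }
  keep <- times <= horizon + 1e-12
  if (!any(abs(times - horizon) < 1e-9)) {
    stop_field("horizon", "must be one of the follow-up times")
  }
  if (anyNA(utilities[keep])) {
    stop("missing utility values: complete the trajectory by imputation before computing QALYs",
         call. = FALSE)
  }
  if (any(utilities[keep] < floor - 1e-9 | utilities[keep] > 1 + 1e-9)) {
    stop_field("utilities", sprintf("must lie in [%g, 1]", floor))
  }
  tt <- times[keep]
  uu <- utilities[keep]
  if (!is.null(death_time) && length(death_time) == 1 && !is.na(death_time) &&
      death_time <= horizon) {
    pre <- tt < death_time
    if (!any(pre)) return(0)
    t_pre <- tt[pre]
    u_pre <- uu[pre]
    area <- trapz(t_pre, u_pre) +
      u_pre[length(u_pre)] * (death_time - t_pre[length(t_pre)]) / 2
    return(area)
  }
  trapz(tt, uu)
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Vectorised AUC over the utility columns of a trial/analysis table.
qalys_for <- function(data, horizon, times = attr(data, "followup_times")) {
  ucols <- paste0("utility_", seq_along(times))
  u <- as.matrix(data[ucols])
  vapply(seq_len(nrow(data)), function(i) {
    auc_qalys(u[i, ], times, horizon, death_time = data$death_time[i])
  }, numeric(1))
}

#' Value set mapping descriptive profiles to utilities
#'
#' A total lookup from the 3125 five-dimension, five-level descriptive
#' profiles (written as digit strings such as `"11223"`) to utility values.
#' Published tariff coefficients are not embedded: supply the lookup as data.
#' By default the constructor requires the full-health profile `"11111"` to
#' map to 1 (the scale anchor); set `anchor = FALSE` for deliberately
#' non-anchored test sets such as a constant value set.
#'
#' @param profiles Character vector of 3125 profiles covering the domain.
#' @param values Utility value per profile.
#' @param anchor Require `value("11111") == 1`?
#' @return A `value_set`.
#' @export
value_set <- function(profiles, values, anchor = TRUE) {
  profiles <- as.character(profiles)
  if (!all(grepl("^[1-5]{5}$", profiles))) {
    stop_field("profiles", "must be five digits, each in 1..5")
  }
  domain <- all_profiles()
  if (!setequal(profiles, domain) || length(profiles) != length(domain)) {
    stop_field("profiles", "must cover all 3125 profiles exactly once")
  }
  v <- as.numeric(values)[match(domain, profiles)]
  if (anchor && abs(v[match("11111", domain)] - 1) > 1e-12) {
    stop_field("values", "full-health profile 11111 must map to 1")
  }
  structure(list(profiles = domain, values = v, anchored = anchor),
            class = "value_set")
}

all_profiles <- function() {
  g <- expand.grid(d5 = 1:5, d4 = 1:5, d3 = 1:5, d2 = 1:5, d1 = 1:5)
  paste0(g$d1, g$d2, g$d3, g$d4, g$d5)
}

#' A simple linear synthetic value set
#'
#' Utility 1 minus a fixed decrement per level above 1 on each dimension;
#' useful for tests and examples in place of a licensed tariff.
#'
#' @param decrement Utility loss per level step per dimension.
#' @return A `value_set`.
#' @export
linear_value_set <- function(decrement = 0.08) {
  p <- all_profiles()
  lv <- vapply(strsplit(p, ""), function(d) sum(as.integer(d) - 1L), numeric(1))
  value_set(p, 1 - decrement * lv)
}

#' Map a descriptive profile to its utility
#'
#' @param profile Five-digit profile string(s), digits in 1..5.
#' @param valueset A [value_set()].
#' @return Utility value(s).
#' @export
map_profile <- function(profile, valueset) {
  if (!inherits(valueset, "value_set")) {
    stop_field("valueset", "must be a value_set()")
  }
  idx <- match(as.character(profile), valueset$profiles)
  if (anyNA(idx)) {
    stop_field("profile", sprintf("profile(s) outside the 5x5 domain: %s",
                                  paste(profile[is.na(idx)], collapse = ", ")))
  }
  valueset$values[idx]
}

#' @rdname value_set_io
#' @export
write_value_set <- function(valueset, path) {
  utils::write.table(
    data.frame(profile = valueset$profiles,
               value = sprintf("%.17g", valueset$values)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write value sets as delimited text
#'
#' Two tab-separated columns: the five level digits and the value. Lookups
#' round-trip exactly.
#'
#' @param valueset A [value_set()].
#' @param path File path.
#' @param anchor Passed to [value_set()] on read.
#' @name value_set_io
#' @export
read_value_set <- function(path, anchor = TRUE) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "numeric"))
  value_set(x$profile, x$value, anchor = anchor)
}
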