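# Costing: turn resource-use quantities into patient-level costs under the
# base micro-costing method and the sensitivity/secondary scenarios
# (Healthcare Resource Group tariffs, theatre-delivered injections, trainee
# surgeons, societal perspective, vial-price override).

#' Unit-cost table constructor
#'
#' @param category Resource category name.
#' @param unit Unit of measurement (free text).
#' @param unit_cost Cost in GBP per unit (>= 0).
#' @param price_year Calendar price year.
#' @param method Which costing method each row belongs to: "micro" or "hrg".
#' @param source_note Provenance note (free text).
#' @return A `unit_cost_table` data frame.
#' @export
unit_cost_table <- function(category, unit, unit_cost, price_year = 2019,
                            method = "micro", source_note = "") {
  check_nonneg(unit_cost, "unit_cost")
  out <- data.frame(category = as.character(category), unit = as.character(unit),
                    unit_cost = unit_cost,
                    price_year = rep_len(price_year, length(category)),
                    method = rep_len(method, length(category)),
                    source_note = rep_len(source_note, length(category)),
                    stringsAsFactors = FALSE)
  class(out) <- c("unit_cost_table", "data.frame")
  out
}

#' Default synthetic unit costs
#'
#' Micro-costing unit costs calibrated so that the default generator yields
#' expected intervention costs of 2166 GBP (limited fasciectomy: theatre
#' session, consultant surgeon minutes, consumables, one wound-clinic review)
#' and 984 GBP (collagenase: one vial, an outpatient injection visit, a
#' manipulation visit, consumables). The line-item composition is synthetic:
#' a published appendix-level cost catalogue is not embedded. Healthcare
#' Resource Group tariff rows (see [hrg_unit_costs()]) are appended so one
#' table serves both costing methods.
#'
#' @return A `unit_cost_table`.
#' @export
default_unit_costs <- function() {
  micro <- unit_cost_table(
    category = c("theatre_session", "theatre_session_minor",
                 "surgeon_consultant_min", "surgeon_trainee_min",
                 "lf_consumable", "wound_clinic", "lf_procedure",
                 "vial", "injection_visit", "manipulation_visit",
                 "colla_consumable",
                 "gp_visit", "physio_visit", "outpatient_visit", "medication"),
    unit = c("session", "session", "minute", "minute", "pack", "visit",
             "procedure", "vial", "visit", "visit", "pack",
             "visit", "visit", "visit", "item"),
    unit_cost = c(1400, 672, 3.50, 2.33, 45, 110, 0,
                  735, 110, 110, 7,
                  39, 54, 110, 8),
    source_note = "synthetic default")
  rbind_cost_tables(micro, hrg_unit_costs())
}

rbind_cost_tables <- function(...) {
  tabs <- list(...)
  cols <- c("category", "unit", "unit_cost", "price_year", "method",
            "source_note")
  out <- do.call(rbind, lapply(tabs, function(t) as.data.frame(t)[cols]))
  class(out) <- c("unit_cost_table", "data.frame")
  out
}

#' Healthcare Resource Group reference tariffs
#'
#' Reads the shipped fixture of per-episode HRG reference costs used by the
#' alternative costing method: HN43B (limited fasciectomy, 2936 GBP), HN46Z
#' (wound clinic / manipulation attendance, 196 GBP) and HN45A (collagenase
#' injection episode, 1143 GBP, drug included).
#'
#' @return A `unit_cost_table` with `method == "hrg"`.
#' @export
hrg_unit_costs <- function() {
  path <- system.file("extdata", "hrg_unit_costs.tsv", package = "dupcea")
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- unit_cost_table(x$category, x$unit, x$unit_cost, x$price_year,
                         method = "hrg", source_note = x$source_note)
  out
}

#' @rdname unit_cost_io
#' @export
write_unit_costs <- function(units, path) {
  utils::write.table(units, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write unit-cost tables as delimited text
#'
#' @param units A `unit_cost_table`.
#' @param path File path.
#' @return `read_unit_costs()` returns a `unit_cost_table`.
#' @name unit_cost_io
#' @export
read_unit_costs <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- unit_cost_table(x$category, x$unit, x$unit_cost, x$price_year,
                         method = x$method, source_note = x$source_note)
  out
}

#' Costing scenario
#'
#' @param method Costing method: `"micro"` (bottom-up micro-costing, the base
#'   case) or `"hrg"` (per-episode reference tariffs for intervention
#'   delivery).
#' @param collagenase_setting Where injections are delivered: `"outpatient"`
#'   (base case) or `"theatre"` (injection visit priced as a minor theatre
#'   session).
#' @param lf_staff Who operates: `"consultant"` (base case) or `"trainee"`
#'   (surgeon minutes priced at the trainee rate).
#' @param perspective `"nhs_pss"` (health and personal social services, base
#'   case) or `"societal"` (adds productivity loss from work absence).
#' @param collagenase_vial_price Optional vial price override in GBP (used by
#'   the price-threshold analysis); `NULL` uses the unit-cost table.
#' @param daily_wage Daily wage for the human-capital productivity loss
#'   valuation (GBP).
#' @return A `costing_scenario`.
#' @export
costing_scenario <- function(method = c("micro", "hrg"),
                             collagenase_setting = c("outpatient", "theatre"),
                             lf_staff = c("consultant", "trainee"),
                             perspective = c("nhs_pss", "societal"),
                             collagenase_vial_price = NULL,
                             daily_wage = 100) {
  method <- match.arg(method)
  collagenase_setting <- match.arg(collagenase_setting)
  lf_staff <- match.arg(lf_staff)
  perspective <- match.arg(perspective)
  if (!is.null(collagenase_vial_price)) {
    check_nonneg(collagenase_vial_price, "collagenase_vial_price")
  }
  check_nonneg(daily_wage, "daily_wage")
  structure(list(method = method, collagenase_setting = collagenase_setting,
                 lf_staff = lf_staff, perspective = perspective,
                 collagenase_vial_price = collagenase_vial_price,
                 daily_wage = daily_wage),
            class = "costing_scenario")
}

# Price per unit for a category under a scenario. HRG replaces the
# intervention-delivery decomposition with per-episode tariffs; categories the
# tariff subsumes (theatre time, staff minutes, drug, consumables) are priced
# at zero under hrg.
HRG_PRICED <- c("lf_procedure", "wound_clinic", "injection_visit",
                "manipulation_visit")

resolve_unit_price <- function(category, units, scenario) {
  lookup <- function(cat, method) {
    i <- which(units$category == cat & units$method == method)
    if (length(i) == 0) {
      stop(sprintf("no unit cost for category '%s' (method '%s')",
                   cat, method), call. = FALSE)
    }
    units$unit_cost[i[1]]
  }
  if (category %in% INTERVENTION_CATEGORIES) {
    if (scenario$method == "hrg") {
      if (category %in% HRG_PRICED) return(lookup(category, "hrg"))
      return(0)
    }
    if (category == "surgeon_min") {
      return(lookup(if (scenario$lf_staff == "trainee")
        "surgeon_trainee_min" else "surgeon_consultant_min", "micro"))
    }
    if (category == "injection_visit" &&
        scenario$collagenase_setting == "theatre") {
      return(lookup("theatre_session_minor", "micro"))
    }
    if (category == "vial" && !is.null(scenario$collagenase_vial_price)) {
      return(scenario$collagenase_vial_price)
    }
  }
  lookup(category, "micro")
}

#' Cost a table of patients under a scenario
#'
#' Multiplies every `qty_<category>_p<period>` column by its scenario-resolved
#' unit cost and sums into buckets: `intervention_cost` (treatment-delivery
#' categories), `followup_cost_p1` / `followup_cost_p2` (primary and secondary
#' care and medications per follow-up year) and `societal_cost` (productivity
#' loss; zero under the NHS/PSS perspective). Masked (`NA`) quantities
#' propagate to `NA` bucket costs so that imputation happens at cost level.
#'
#' @param data A `trial_data` frame (or any data frame with `qty_*` columns
#'   and, for the societal perspective, `absence_days`).
#' @param units A `unit_cost_table` (default [default_unit_costs()]).
#' @param scenario A [costing_scenario()].
#' @return Data frame with one row per patient and the cost buckets above.
#' @export
cost_trial <- function(data, units = default_unit_costs(),
                       scenario = costing_scenario()) {
  qcols <- grep("^qty_", names(data), value = TRUE)
  if (length(qcols) == 0) stop("no qty_* resource-use columns found")
  for (cl in qcols) {
    v <- data[[cl]]
    if (any(!is.na(v) & v < 0)) {
      stop(sprintf("negative resource quantity in '%s'", cl), call. = FALSE)
    }
  }
  n <- nrow(data)
  intervention <- numeric(n)
  followup <- matrix(0, n, 2)
  for (cl in qcols) {
    category <- sub("^qty_(.*)_p[0-9]+$", "\\1", cl)
    period <- as.integer(sub("^.*_p([0-9]+)$", "\\1", cl))
    price <- resolve_unit_price(category, units, scenario)
    contrib <- data[[cl]] * price
    if (category %in% INTERVENTION_CATEGORIES) {
      intervention <- intervention + contrib
    } else {
      followup[, period] <- followup[, period] + contrib
    }
  }
  societal <- if (scenario$perspective == "societal") {
    productivity_loss(data$absence_days, scenario$daily_wage)
  } else {
    numeric(n)
  }
  data.frame(intervention_cost = intervention,
             followup_cost_p1 = followup[, 1],
             followup_cost_p2 = followup[, 2],
             societal_cost = societal)
}

#' Cost a single patient record
#'
#' Single-record wrapper around [cost_trial()].
#'
#' @param record One-row data frame with `qty_*` columns.
#' @inheritParams cost_trial
#' @return Named list with `intervention_cost`, `followup_cost` (sum over
#'   periods) and `societal_cost`.
#' @examples
#' rec <- data.frame(qty_lf_procedure_p1 = 1, qty_wound_clinic_p1 = 1)
#' cost_patient(rec, scenario = costing_scenario(method = "hrg"))
#' @export
cost_patient <- function(record, units = default_unit_costs(),
                         scenario = costing_scenario()) {
  stopifnot(nrow(record) == 1)
  x <- cost_trial(record, units, scenario)
  list(intervention_cost = x$intervention_cost,
       followup_cost = x$followup_cost_p1 + x$followup_cost_p2,
       societal_cost = x$societal_cost)
}

#' Adjust an amount between price years
#'
#' Multiplies by the product of annual inflation factors between the two
#' years; the identity when the years are equal, the inverse product when
#' deflating to an earlier year.
#'
#' @param amount Amount in GBP.
#' @param from_year,to_year Calendar price years.
#' @param index Named numeric vector of annual factors: `index["2018"]` is the
#'   factor taking 2018 prices to 2019 prices.
#' @return Adjusted amount.
#' @examples
#' inflate(100, 2018, 2020, c("2018" = 1.02, "2019" = 1.03))
#' @export
inflate <- function(amount, from_year, to_year, index = NULL) {
  if (from_year == to_year) return(amount)
  lo <- min(from_year, to_year)
  hi <- max(from_year, to_year)
  years <- as.character(seq.int(lo, hi - 1))
  if (is.null(index) || !all(years %in% names(index))) {
    missing_years <- if (is.null(index)) years else setdiff(years, names(index))
    stop(sprintf("no inflation index entry for year(s): %s",
                 paste(missing_years, collapse = ", ")), call. = FALSE)
  }
  f <- prod(index[years])
  if (to_year > from_year) amount * f else amount / f
}

#' Productivity loss from work absence (human-capital approach)
#'
#' @param absence_days Work days lost (>= 0).
#' @param daily_wage Daily wage in GBP (>= 0).
#' @return Productivity loss in GBP; only enters totals under the societal
#'   perspective.
#' @export
productivity_loss <- function(absence_days, daily_wage) {
  check_nonneg(absence_days, "absence_days")
  check_nonneg(daily_wage, "daily_wage")
  absence_days * daily_wage
}
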