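# Synthetic life tables: a Gompertz-like stand-in for a national all-cause
# mortality registry, by single year of age and sex.

#' Generate a synthetic life table
#'
#' Builds an annual death-probability table by age and sex with a
#' geometrically increasing hazard, `q(age) = min(1, base_q * growth^(age -
#' start_age))`, optionally scaled down for women. It stands in for a national
#' statistics registry table in analyses where the real table is not
#' distributable; any table with the same columns can be supplied instead.
#'
#' @param base_q Annual death probability at `start_age` (in (0, 1]).
#' @param growth Multiplicative yearly hazard growth factor (>= 1).
#' @param max_age Last age covered (years).
#' @param start_age First age covered (years, default 18).
#' @param female_factor Multiplier applied to the female hazard before
#'   capping at 1 (default 1 = no sex differential).
#' @return A `life_table`: data frame with columns `age`, `sex` ("F"/"M") and
#'   `qx`, covering every age from `start_age` to `max_age`.
#' @examples
#' lt <- generate_life_table(0.0004, 1.083, max_age = 85)
#' head(lt)
#' @export
generate_life_table <- function(base_q, growth, max_age, start_age = 18,
                                female_factor = 1) {
  if (!is.numeric(base_q) || length(base_q) != 1 || base_q <= 0 || base_q > 1) {
    stop_field("base_q", "must be in (0, 1]")
  }
  if (!is.numeric(growth) || length(growth) != 1 || growth < 1) {
    stop_field("growth", "must be >= 1")
  }
  if (max_age < start_age) {
    stop_field("max_age", "must be >= start_age")
  }
  check_nonneg(female_factor, "female_factor")
  ages <- seq.int(start_age, max_age)
  qm <- pmin(1, base_q * growth^(ages - start_age))
  qf <- pmin(1, female_factor * qm)
  out <- data.frame(
    age = rep(ages, 2),
    sex = rep(c("F", "M"), each = length(ages)),
    qx  = c(qf, qm),
    stringsAsFactors = FALSE
  )
  class(out) <- c("life_table", "data.frame")
  out
}

as_life_table <- function(x) {
  if (!all(c("age", "sex", "qx") %in% names(x))) {
    stop_field("life_table", "needs columns age, sex, qx")
  }
  check_prob(x$qx, "qx")
  class(x) <- unique(c("life_table", class(x)))
  x
}

#' Look up annual death probabilities in a life table
#'
#' @param life_table A `life_table` (see [generate_life_table()]).
#' @param age Integer ages (years).
#' @param sex "F" or "M", recycled against `age`.
#' @return Vector of annual death probabilities.
#' @export
life_table_q <- function(life_table, age, sex) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  key <- paste(life_table$age, life_table$sex)
  idx <- match(paste(floor(age), sex), key)
  if (anyNA(idx)) {
    stop_field("age", sprintf("age %s (%s) outside the life table range",
                              paste(age[is.na(idx)], collapse = ", "),
                              paste(sex[is.na(idx)], collapse = ", ")))
  }
  life_table$qx[idx]
}

#' @rdname life_table_io
#' @export
write_life_table <- function(life_table, path) {
  out <- as.data.frame(life_table)
  out$qx <- sprintf("%.17g", out$qx)   # lossless round trip
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write life tables as delimited text
#'
#' Plain tab-separated text with header `age`, `sex`, `qx`; round-trips
#' losslessly.
#'
#' @param life_table A `life_table`.
#' @param path File path.
#' @return `read_life_table()` returns a `life_table`;
#'   `write_life_table()` returns `path` invisibly.
#' @name life_table_io
#' @export
read_life_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  as_life_table(x)
}
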