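# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop_field(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_field(field, "must be non-negative")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's random number
#' generator state afterwards, so seeded package functions do not perturb the
#' session RNG stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed A single integer seed, or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Round half away from zero
#'
#' Presentation-layer rounding used for all printed tables: halves round away
#' from zero (so 0.0515 -> 0.052 at three decimals), unlike [round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(0.0515, 3)
#' round_half_away(-1090.5, 0)
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Formatting helpers for table rendering (pounds to the whole pound, QALYs and
# NHB to 3 dp, probabilities to 1 dp percent).
format_gbp <- function(x) {
  paste0(ifelse(x < 0, "-", ""), "£",
         formatC(abs(round_half_away(x, 0)), format = "f", digits = 0))
}

format_qaly <- function(x) {
  formatC(round_half_away(x, 3), format = "f", digits = 3)
}

format_pct <- function(x) {
  paste0(formatC(round_half_away(100 * x, 1), format = "f", digits = 1), "%")
}

# Tiny polynomial rolling hash of a deparsed object; stamps pipeline
# artifacts so a rerun with the same configuration is recognisable.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Arm handling: incremental direction is collagenase - LF throughout.
ARM_LEVELS <- c("LF", "collagenase")

as_arm <- function(x) {
  f <- factor(as.character(x), levels = ARM_LEVELS)
  if (anyNA(f)) stop_field("arm", "must be 'LF' or 'collagenase'")
  f
}
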