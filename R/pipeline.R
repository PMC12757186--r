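# Orchestration and reporting: seeded end-to-end runs over synthetic or
# user-supplied data, and rendering of publication-style results tables
# (costs to the whole pound, QALYs/NHB to three decimals, probabilities to
# one decimal percent; halves round away from zero, at the presentation
# layer only).

#' Pipeline run configuration
#'
#' @param seed Master seed for every stage.
#' @param outdir Output directory (created if needed).
#' @param n_per_arm Patients per arm for the synthetic stage.
#' @param data Optional `trial_data` to analyse instead of simulating.
#' @param scenarios Named list of [costing_scenario()]s to run (first one is
#'   the base case).
#' @param analyses Which stages to run: any of `"cea"`, `"model"`, `"psa"`.
#' @param lambdas Reporting thresholds (GBP/QALY).
#' @param mi_m,boot_reps,psa_n Stage sizes: imputations, bootstrap resamples
#'   per imputation, PSA iterations.
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("dupcea-run-"),
                       n_per_arm = 336, data = NULL,
                       scenarios = list(base = costing_scenario()),
                       analyses = c("cea", "model"),
                       lambdas = c(20000, 30000),
                       mi_m = 25, boot_reps = 200, psa_n = 1000) {
  if (any(lambdas <= 0)) stop_field("lambdas", "must be positive")
  analyses <- match.arg(analyses, c("cea", "model", "psa"), several.ok = TRUE)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 n_per_arm = n_per_arm, data = data, scenarios = scenarios,
                 analyses = analyses, lambdas = lambdas, mi_m = mi_m,
                 boot_reps = boot_reps, psa_n = psa_n),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order: simulate (or load) the
#' patient table, apply missingness, run the within-trial CEA per scenario,
#' run the deterministic Markov model and optionally the PSA, then render and
#' write all tables. Every artifact is stamped with the configuration hash
#' and seed; a rerun with the same configuration is bit-identical.
#'
#' @param config A [run_config()].
#' @return A `run_bundle` (invisibly): list with the fitted objects, the
#'   rendered tables, `outdir` and the stamp.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop_field("config", "must be run_config()")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("config %s seed %d", config_hash(config[
    setdiff(names(config), "outdir")]), config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dat <- stage("simulate", {
    if (!is.null(config$data)) config$data else {
      cfg <- trial_config(n_per_arm = config$n_per_arm, seed = config$seed)
      apply_missingness(generate_trial(cfg), cfg$missingness,
                        seed = config$seed + 1L)
    }
  })
  bundle <- list(data = dat, config = config, stamp = stamp)
  if ("cea" %in% config$analyses) {
    bundle$cea <- stage("cea", {
      lapply(config$scenarios, function(sc) {
        cea_trial(dat, scenario = sc,
                  mi = mi_config(m = config$mi_m, seed = config$seed),
                  boot = bootstrap_config(config$boot_reps),
                  lambdas = config$lambdas, seed = config$seed)
      })
    })
  }
  if (any(c("model", "psa") %in% config$analyses)) {
    bundle$model <- stage("model", markov_cea(lambdas = config$lambdas))
  }
  if ("psa" %in% config$analyses) {
    bundle$psa <- stage("psa", run_psa(
      priors = psa_priors(n_iterations = config$psa_n,
                          seed = config$seed),
      lambdas = config$lambdas))
  }
  bundle$tables <- render_tables(bundle)
  stage("write", write_bundle(bundle))
  class(bundle) <- "run_bundle"
  invisible(bundle)
}

#' Render results tables
#'
#' Formats fitted results the way cost-effectiveness tables are printed:
#' costs rounded to whole pounds, QALYs and NHB to three decimals,
#' probabilities to one decimal percent, halves away from zero. Returns both
#' display tables (character) and the machine-readable numeric values.
#'
#' @param bundle A list with any of `cea` (named list of `cea_fit`), `model`
#'   (`markov_cea`), `psa` (`psa_result`), as built by [run_pipeline()].
#' @return List with `display` (character data frames) and `machine`
#'   (numeric lists mirroring the display values, reloadable via JSON).
#' @export
render_tables <- function(bundle) {
  display <- list()
  machine <- list()
  if (!is.null(bundle$cea)) {
    rows <- list()
    for (sc in names(bundle$cea)) {
      fit <- bundle$cea[[sc]]
      for (res in fit$results) {
        nm <- sprintf("%s, %g-year", sc, res$horizon)
        machine$cea[[sc]][[as.character(res$horizon)]] <- list(
          delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
          ci_cost = res$ci_cost, ci_qaly = res$ci_qaly,
          icer = res$icer$ratio, icer_label = res$icer$label,
          nhb = as.list(res$nhb), p_ce = as.list(res$p_ce))
        rows[[nm]] <- data.frame(
          analysis = nm,
          incremental_cost = sprintf("%s (%s to %s)",
                                     format_gbp(res$delta_cost),
                                     format_gbp(res$ci_cost[1]),
                                     format_gbp(res$ci_cost[2])),
          incremental_qalys = sprintf("%s (%s to %s)",
                                      format_qaly(res$delta_qaly),
                                      format_qaly(res$ci_qaly[1]),
                                      format_qaly(res$ci_qaly[2])),
          icer = res$icer$label,
          nhb = paste(vapply(res$nhb, format_qaly, character(1)),
                      collapse = " / "),
          p_ce = paste(vapply(res$p_ce, format_pct, character(1)),
                       collapse = " / "),
          stringsAsFactors = FALSE)
      }
    }
    display$cea <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (!is.null(bundle$model)) {
    cmp <- bundle$model$comparison
    disp <- data.frame(
      horizon = cmp$horizon,
      cost_LF = format_gbp(cmp$cost_LF),
      qaly_LF = format_qaly(cmp$qaly_LF),
      cost_collagenase = format_gbp(cmp$cost_collagenase),
      qaly_collagenase = format_qaly(cmp$qaly_collagenase),
      incremental_cost = format_gbp(cmp$delta_cost),
      incremental_qalys = format_qaly(cmp$delta_qaly),
      stringsAsFactors = FALSE)
    for (l in bundle$model$lambdas) {
      disp[[paste0("nhb_", l)]] <- format_qaly(cmp[[paste0("nhb_", l)]])
    }
    display$model <- disp
    machine$model <- cmp
  }
  if (!is.null(bundle$psa)) {
    display$psa <- data.frame(
      horizon = bundle$psa$ceac$horizon,
      lambda = format_gbp(bundle$psa$ceac$lambda),
      p_ce = format_pct(bundle$psa$ceac$p_ce),
      stringsAsFactors = FALSE)
    machine$psa <- bundle$psa$ceac
  }
  list(display = display, machine = machine)
}

write_bundle <- function(bundle) {
  out <- bundle$config$outdir
  hdr <- paste0("# ", bundle$stamp)
  for (nm in names(bundle$tables$display)) {
    path <- file.path(out, paste0(nm, "_table.tsv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    suppressWarnings(
      utils::write.table(bundle$tables$display[[nm]], con, sep = "\t",
                         row.names = FALSE, quote = FALSE))
    close(con)
  }
  jsonlite::write_json(
    c(list(stamp = bundle$stamp), bundle$tables$machine),
    file.path(out, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("Pipeline run (", x$stamp, ")\n", sep = "")
  cat("Outputs in:", x$config$outdir, "\n")
  for (nm in names(x$tables$display)) {
    cat("\n==", nm, "==\n")
    print(x$tables$display[[nm]], row.names = FALSE)
  }
  invisible(x)
}
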