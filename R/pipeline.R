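#' Read a scenario configuration file
#'
#' YAML (or JSON, a YAML subset) configuration whose keys mirror the
#' constructor arguments of [model_params()], [unit_costs()],
#' [cascade_counts()], [thresholds()], [dsa_spec()] and [psa_spec()] under
#' the sections `model_params`, `unit_costs`, `cascade_counts`,
#' `thresholds`, `dsa`, `psa`. The `life_table` section is either
#' `file: <path>` (read with [read_life_table()]) or `synthetic:` with
#' Gompertz-Makeham parameters for [synth_life_table()]. Any key not set
#' falls back to the scenario default and is listed via `message()`, so
#' every assumption in effect is visible at run time.
#'
#' @param path configuration file path.
#' @param quiet suppress the defaulted-keys message.
#' @return A `cea_scenario`.
#' @seealso [write_scenario_config()]
#' @export
read_scenario_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  build_section <- function(section, constructor) {
    supplied <- cfg[[section]]
    if (is.null(supplied)) supplied <- list()
    known <- names(formals(constructor))
    unknown <- setdiff(names(supplied), known)
    if (length(unknown)) {
      stop(sprintf("config section `%s`: unknown field(s) %s",
                   section, paste0("`", unknown, "`", collapse = ", ")),
           call. = FALSE)
    }
    defaulted <- setdiff(known, names(supplied))
    if (!quiet && length(defaulted)) {
      message(sprintf("config `%s`: defaults used for %s",
                      section, paste(defaulted, collapse = ", ")))
    }
    do.call(constructor, supplied)
  }
  lt <- if (!is.null(cfg$life_table$file)) {
    read_life_table(cfg$life_table$file)
  } else if (!is.null(cfg$life_table$synthetic)) {
    do.call(synth_life_table, cfg$life_table$synthetic)
  } else {
    if (!quiet) message("config `life_table`: none supplied, using the synthetic fixture table")
    synth_life_table()
  }
  sc <- structure(list(
    name = if (!is.null(cfg$name)) cfg$name else "unnamed",
    params = build_section("model_params", model_params),
    unit_costs = build_section("unit_costs", unit_costs),
    counts = build_section("cascade_counts", cascade_counts),
    thresholds = build_section("thresholds", thresholds),
    life_table = lt,
    dsa = build_section("dsa", dsa_spec),
    psa = build_section("psa", psa_spec)
  ), class = "cea_scenario")
  sc
}

#' Write a scenario configuration file
#'
#' Serialises every scenario section to YAML; [read_scenario_config()]
#' round-trips it without loss (the life table is embedded as a synthetic
#' spec reference or written alongside).
#'
#' @param scenario a `cea_scenario`.
#' @param path output path; the life table is written next to it as
#'   `<path>_life_table.csv` and referenced from the config.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  lt_path <- paste0(tools::file_path_sans_ext(path), "_life_table.csv")
  write_life_table(scenario$life_table, lt_path)
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1L))]
  }
  cfg <- list(
    name = scenario$name,
    model_params = strip(scenario$params),
    unit_costs = strip(scenario$unit_costs),
    cascade_counts = strip(scenario$counts),
    thresholds = strip(scenario$thresholds),
    dsa = strip(scenario$dsa),
    psa = strip(scenario$psa),
    life_table = list(file = lt_path)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis for one scenario
#'
#' Life-table preparation, Markov model in both arms, cost ledger, and the
#' cost-effectiveness result, assembled into a run report. With `out_dir`
#' set, writes the result JSON, the ledger CSV and both cohort-trace CSVs.
#' All rounding in the report is presentation-only and flagged as such;
#' every number is traceable to a ledger line or model output.
#'
#' @param scenario a `cea_scenario`, or the path of a configuration file.
#' @param out_dir optional output directory (created if missing).
#' @return An object of class `run_report`: list with `scenario_name`,
#'   `fit` (the [stdr_markov] object), `cea` (the [cea_result]), `totals`
#'   (ledger totals), `switches` (design switches in effect), and `files`
#'   (paths written, if any).
#' @export
run_scenario <- function(scenario, out_dir = NULL) {
  if (is.character(scenario)) scenario <- read_scenario_config(scenario)
  stopifnot(inherits(scenario, "cea_scenario"))
  fit <- stdr_markov(scenario$params, scenario$life_table)
  ledger <- build_cost_ledger(scenario$unit_costs, scenario$counts)
  res <- cea_result(ledger, max(fit$qaly_gain_stdr, 0),
                    max(fit$qaly_gain_cataract, 0), scenario$thresholds)
  p <- scenario$params
  report <- structure(list(
    scenario_name = scenario$name,
    fit = fit,
    cea = res,
    totals = cost_totals(ledger),
    le_untreated = fit$le_untreated,
    le_treated = fit$le_treated,
    qaly_gain_stdr = fit$qaly_gain_stdr,
    qaly_gain_cataract = fit$qaly_gain_cataract,
    switches = list(half_cycle = p$half_cycle,
                    uplift_scale = p$uplift_scale,
                    blind_uplift_combined = p$blind_uplift_combined,
                    stdr_utility_decline = p$stdr_utility_decline,
                    discounting_starts = "cycle 1",
                    rounding = "presentation only (nearest INR 5 per patient, 0.1 million totals, integer QALYs)"),
    files = character(0)
  ), class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- c(result = file.path(out_dir, "result.json"),
           ledger = file.path(out_dir, "ledger.csv"),
           trace_treated = file.path(out_dir, "trace_treated.csv"),
           trace_untreated = file.path(out_dir, "trace_untreated.csv"))
    writeLines(report_json(report), f[["result"]])
    write_cost_ledger(ledger, f[["ledger"]])
    utils::write.csv(trace_as_df(fit$trace_treated), f[["trace_treated"]], row.names = FALSE)
    utils::write.csv(trace_as_df(fit$trace_untreated), f[["trace_untreated"]], row.names = FALSE)
    report$files <- f
  }
  report
}

#' Canonical JSON body of a run report
#'
#' Deterministic serialisation of the report's numbers (no file paths, no
#' timestamps): the same scenario always yields a byte-identical body.
#'
#' @param report a `run_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "run_report"))
  x <- list(
    scenario = report$scenario_name,
    totals_inr = report$totals,
    life_expectancy_years = list(untreated = report$le_untreated,
                                 treated = report$le_treated),
    qaly_gain_per_person = list(stdr = report$qaly_gain_stdr,
                                cataract = report$qaly_gain_cataract),
    qalys = report$cea$qalys,
    avg_qaly_per_treated = report$cea$avg_qaly_per_treated,
    icer_inr_per_qaly = as.numeric(report$cea$icer),
    classification = report$cea$classification,
    switches = report$switches
  )
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report: scenario \"%s\"\n\n", x$scenario_name))
  print(x$cea)
  cat(sprintf("\n  life expectancy at %d: %.2f yr untreated, %.2f yr treated\n",
              x$fit$params$start_age, x$le_untreated, x$le_treated))
  cat(sprintf("  per-person QALY gain: %.3f laser, %.3f cataract\n",
              x$qaly_gain_stdr, x$qaly_gain_cataract))
  if (length(x$files)) {
    cat("  files written:\n")
    for (f in x$files) cat("   ", f, "\n")
  }
  invisible(x)
}

#' Run the one-way sensitivity analysis and write the tornado table
#'
#' @param scenario a `cea_scenario` or config path.
#' @param out_dir optional output directory for `tornado.csv`
#'   (`parameter,low_icer,high_icer,span`, sorted by descending span).
#' @return The `tornado` table.
#' @export
run_dsa <- function(scenario, out_dir = NULL) {
  if (is.character(scenario)) scenario <- read_scenario_config(scenario)
  tor <- one_way_dsa(scenario)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(tor), file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
  }
  tor
}

#' Run the probabilistic sensitivity analysis and write its tables
#'
#' Draws, CEAC and the probability of cost-effectiveness at the headline
#' willingness-to-pay threshold (with its binomial Monte-Carlo standard
#' error).
#'
#' @param scenario a `cea_scenario` or config path.
#' @param out_dir optional output directory for `psa_draws.csv` and
#'   `ceac.csv`.
#' @param seed optional root-seed override for the PSA.
#' @return List with `draws` (`psa_draws`), `ceac` (`ceac`) and
#'   `prob_at_144k` (see [prob_cost_effective()]).
#' @export
run_psa_report <- function(scenario, out_dir = NULL, seed = NULL) {
  if (is.character(scenario)) scenario <- read_scenario_config(scenario)
  spec <- scenario$psa
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  draws <- run_psa(scenario, spec)
  cv <- ceac(draws)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(draws), file.path(out_dir, "psa_draws.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cv), file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
  }
  list(draws = draws, ceac = cv, prob_at_144k = prob_cost_effective(draws))
}
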