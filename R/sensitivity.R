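# One-way deterministic sensitivity analysis and named scenarios.

COMPONENT_PATHS <- c("costs.hospitalization", "costs.birth", "costs.outpatient_care")

# Scale a cost component across every branch of both strategies; per-patient
# costs are the component sums, so they update with it.
scale_component <- function(config, component, factor) {
  col <- paste0("comp_", component)
  for (s in names(config$strategies)) {
    df <- config$strategies[[s]]
    df[[col]] <- df[[col]] * factor
    df$per_patient <- df$comp_outpatient + df$comp_hospitalization + df$comp_birth
    df$total_cost <- df$n * df$per_patient
    config$strategies[[s]] <- df
  }
  config
}

#' Apply a one-way sensitivity modifier
#'
#' Returns a new configuration with one parameter scaled (`mode = "relative"`,
#' by `1 + modifier`) or replaced (`mode = "absolute"`); the input
#' configuration is untouched. Besides scalar parameter paths, the component
#' paths `costs.hospitalization`, `costs.birth` and `costs.outpatient_care`
#' scale that cost component across every branch of both strategies
#' (relative mode only).
#'
#' @param config A `pe_config`.
#' @param spec List with `parameter_path`, `modifier`, `mode` and optionally
#'   `label`.
#' @return A modified `pe_config`.
#' @export
apply_modifier <- function(config, spec) {
  path <- spec$parameter_path
  mode <- if (is.null(spec$mode)) "relative" else spec$mode
  modifier <- as.numeric(spec$modifier)
  if (!mode %in% c("relative", "absolute")) stop_config("unknown modifier mode '%s'", mode)
  if (mode == "relative" && modifier <= -1) {
    stop_config("relative modifiers must exceed -1 (got %s)", format(modifier))
  }
  if (path %in% COMPONENT_PATHS) {
    if (mode != "relative") {
      stop_config("component path '%s' supports relative modifiers only", path)
    }
    component <- sub("^costs\\.", "", path)
    if (component == "outpatient_care") component <- "outpatient"
    return(scale_component(config, component, 1 + modifier))
  }
  value <- config_get(config, path)
  new_value <- if (mode == "relative") value * (1 + modifier) else modifier
  config_set(config, path, new_value)
}

# Probability-touching specs are evaluated in probability mode so the changed
# rates actually reallocate the cohort.
spec_mode <- function(path) {
  if (grepl("^(strata|probability)\\.", path)) "probability" else "counts"
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the strategy comparison once per specification and records the
#' per-patient saving of the testing strategy. Specifications touching
#' admission probabilities are evaluated in probability mode (and compared
#' against the probability-mode base saving); cost specifications keep the
#' exact counts-mode base case. Entries are sorted by absolute deviation from
#' the base saving, descending, with ties broken by label.
#'
#' @param config A `pe_config`.
#' @param specs List of modifier specifications (default: the configuration's
#'   `sensitivity.one_way` block).
#' @return Data frame of tornado entries: `label`, `parameter_path`, `mode`,
#'   `per_patient_saving`, `delta_vs_base`.
#' @export
one_way <- function(config, specs = config$sensitivity$one_way) {
  if (length(specs) == 0L) {
    return(data.frame(label = character(), parameter_path = character(),
                      mode = character(), per_patient_saving = numeric(),
                      delta_vs_base = numeric(), stringsAsFactors = FALSE))
  }
  base_saving <- c(
    counts = per_patient_saving(config, "counts"),
    probability = per_patient_saving(config, "probability")
  )
  rows <- lapply(specs, function(sp) {
    m <- spec_mode(sp$parameter_path)
    s <- per_patient_saving(apply_modifier(config, sp), m)
    data.frame(label = as.character(sp$label),
               parameter_path = as.character(sp$parameter_path),
               mode = m,
               per_patient_saving = s,
               delta_vs_base = s - base_saving[[m]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$delta_vs_base), out$label), ]
  rownames(out) <- NULL
  out
}

#' Tornado summary per parameter
#'
#' Collapses one-way entries to one row per parameter path, keeping the
#' largest absolute deviation across that parameter's variations -- the bar
#' length of a tornado diagram.
#'
#' @param entries Result of [one_way()].
#' @return Data frame `parameter_path`, `max_abs_delta`, sorted descending.
#' @export
tornado_summary <- function(entries) {
  if (nrow(entries) == 0L) {
    return(data.frame(parameter_path = character(), max_abs_delta = numeric()))
  }
  agg <- stats::aggregate(abs(entries$delta_vs_base),
                          by = list(parameter_path = entries$parameter_path), FUN = max)
  names(agg)[2] <- "max_abs_delta"
  agg <- agg[order(-agg$max_abs_delta, agg$parameter_path), ]
  rownames(agg) <- NULL
  agg
}

# Cohort size of a retest population.
retest_population_size <- function(config, population) {
  test_df <- config$strategies$test
  switch(population,
    all = as.numeric(config$cohort_size),
    low_setting = test_df$n[test_df$branch_id == "low"],
    intermediate_4x = test_df$n[test_df$branch_id == "intermediate"],
    stop_config("unknown retest population '%s'", population)
  )
}

#' Run a named scenario analysis
#'
#' `exclude_birth_costs` removes the birth component from every branch of both
#' strategies and re-compares. `retest` adds
#' `retest_fraction x population x tests_per_retested_patient` extra test
#' determinations to the testing strategy's test costs; retests change test
#' spending only (no management-pathway shift).
#'
#' @param config A `pe_config`.
#' @param scenario List with `name` (`"exclude_birth_costs"` or `"retest"`),
#'   optional `label`, and for retests `retest_fraction`, `retest_population`
#'   (`"low_setting"`, `"all"`, `"intermediate_4x"`) and
#'   `tests_per_retested_patient`.
#' @return One-row data frame: `label`, `per_patient_saving`, `delta_vs_base`.
#' @export
run_scenario <- function(config, scenario) {
  base_saving <- per_patient_saving(config, "counts")
  name <- scenario$name
  label <- if (is.null(scenario$label)) name else scenario$label
  saving <- switch(name,
    exclude_birth_costs = {
      per_patient_saving(scale_component(config, "birth", 0), "counts")
    },
    retest = {
      frac <- as.numeric(scenario$retest_fraction)
      if (is.na(frac) || frac < 0 || frac > 1) {
        stop_config("retest_fraction must lie in [0, 1]")
      }
      per_test <- as.numeric(scenario$tests_per_retested_patient)
      pop <- retest_population_size(config, scenario$retest_population)
      cfg <- config_set(config, "costs.extra_tests", frac * pop * per_test)
      per_patient_saving(cfg, "counts")
    },
    stop_config("unknown scenario '%s'", name)
  )
  data.frame(label = label, per_patient_saving = saving,
             delta_vs_base = saving - base_saving, stringsAsFactors = FALSE)
}

#' Run the full configured sensitivity suite
#'
#' All one-way entries plus all named scenarios, in one tornado-ready table.
#'
#' @param config A `pe_config`.
#' @return Data frame with `label`, `per_patient_saving`, `delta_vs_base` and
#'   `kind` (`"one_way"` or `"scenario"`).
#' @export
sensitivity_suite <- function(config) {
  ow <- one_way(config)
  ow$kind <- if (nrow(ow)) "one_way" else character(0)
  sc <- do.call(rbind, lapply(config$sensitivity$scenarios, run_scenario, config = config))
  sc$kind <- "scenario"
  keep <- c("label", "per_patient_saving", "delta_vs_base", "kind")
  out <- rbind(ow[, keep], sc[, keep])
  rownames(out) <- NULL
  out
}
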