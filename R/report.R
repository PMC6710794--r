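# Report writers, run manifests, and command-line entry points.

fmt_eur <- function(x) sprintf("%.2f", x)

#' Write the strategy-comparison table as CSV
#'
#' Branch rows followed by total rows (medical costs, test evaluation,
#' overall, per patient), with N and cost per strategy and the difference.
#' Monetary cells carry two decimals.
#'
#' @param comparison A `pe_comparison`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  a <- comparison$a$branch_results
  b <- comparison$b$branch_results
  rows <- data.frame(
    row = b$branch_id,
    label = b$label,
    n_no_test = b$n,
    cost_no_test = fmt_eur(b$total_cost),
    n_test = a$n,
    cost_test = fmt_eur(a$total_cost),
    difference = fmt_eur(a$total_cost - b$total_cost),
    stringsAsFactors = FALSE
  )
  totals <- data.frame(
    row = c("total_medical_costs", "test_evaluation", "total", "per_patient"),
    label = c("Total medical costs", "sFlt-1/PlGF evaluation", "Total", "Per patient"),
    n_no_test = c(comparison$b$cohort_size, 0, comparison$b$cohort_size, comparison$b$cohort_size),
    cost_no_test = fmt_eur(c(comparison$b$medical_cost_total, comparison$b$test_cost_total,
                             comparison$b$overall_total, comparison$b$per_patient)),
    n_test = c(comparison$a$cohort_size, comparison$a$cohort_size,
               comparison$a$cohort_size, comparison$a$cohort_size),
    cost_test = fmt_eur(c(comparison$a$medical_cost_total, comparison$a$test_cost_total,
                          comparison$a$overall_total, comparison$a$per_patient)),
    difference = fmt_eur(c(comparison$delta_medical,
                           comparison$a$test_cost_total - comparison$b$test_cost_total,
                           comparison$delta_total, comparison$delta_per_patient)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(rbind(rows, totals), path, row.names = FALSE)
  invisible(path)
}

#' Write the budget-impact table as CSV
#' @param bia A `pe_budget_impact`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bia_csv <- function(bia, path) {
  py <- bia$per_year
  out <- data.frame(
    year = py$year,
    n_no_test = py$n_no_test,
    cost_no_test_patients = fmt_eur(py$cost_no_test_patients),
    n_test = py$n_test,
    cost_test_patients = fmt_eur(py$cost_test_patients),
    mixed_total = fmt_eur(py$mixed_total),
    counterfactual_no_test_total = fmt_eur(py$counterfactual_no_test_total),
    difference = fmt_eur(py$difference),
    stringsAsFactors = FALSE
  )
  total_row <- data.frame(
    year = NA_integer_,
    n_no_test = sum(py$n_no_test),
    cost_no_test_patients = fmt_eur(sum(py$cost_no_test_patients)),
    n_test = sum(py$n_test),
    cost_test_patients = fmt_eur(sum(py$cost_test_patients)),
    mixed_total = fmt_eur(sum(py$mixed_total)),
    counterfactual_no_test_total = fmt_eur(sum(py$counterfactual_no_test_total)),
    difference = fmt_eur(bia$cumulative_difference),
    stringsAsFactors = FALSE
  )
  utils::write.csv(rbind(out, total_row), path, row.names = FALSE)
  invisible(path)
}

#' Write tornado-ready sensitivity results as CSV
#' @param entries Data frame from [one_way()] or [sensitivity_suite()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado_csv <- function(entries, path) {
  out <- entries
  for (col in c("per_patient_saving", "delta_vs_base")) out[[col]] <- fmt_eur(out[[col]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write simulated patient records as CSV
#' @param records Data frame from [simulate_patients()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(records, path) {
  out <- records
  for (col in c("pathway_cost", "cost_total")) out[[col]] <- fmt_eur(out[[col]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read back a CSV written by the package's writers
#' @param path CSV path.
#' @return Data frame.
#' @export
read_model_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Digest of a configuration's content
#'
#' MD5 over a canonical text serialization of the configuration (excluding
#' its on-disk location), so the digest changes exactly when the parameter
#' content changes.
#'
#' @param config A `pe_config`.
#' @return Hex digest string.
#' @export
config_digest <- function(config) {
  x <- unclass(config)
  x$source_path <- NULL
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")), tf)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' Records the command, configuration digest, seed and output paths so any
#' reported number is reproducible from (digest, command, seed).
#'
#' @param command Command name.
#' @param config A `pe_config`.
#' @param outputs Character vector of output file paths.
#' @param path Manifest JSON path.
#' @param seed Seed used, or `NULL` for deterministic commands.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(command, config, outputs, path, seed = NULL) {
  manifest <- list(
    command = command,
    config_digest = config_digest(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    outputs = as.list(basename(outputs))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

load_validated <- function(config_path) {
  config <- load_config(config_path)
  v <- validate_config(config)
  if (!v$ok) {
    bad <- v$messages[v$messages$severity == "error", ]
    stop_config("configuration invalid: %s",
                paste(sprintf("%s (%s)", bad$text, bad$path), collapse = "; "))
  }
  config
}

#' Run the strategy comparison and write its reports
#'
#' @param config_path Path to a configuration YAML.
#' @param outdir Output directory (created if needed).
#' @param mode Allocation mode.
#' @return Paths of the written files, invisibly.
#' @export
run_compare_report <- function(config_path = base_case_path(), outdir = ".",
                               mode = "counts") {
  config <- load_validated(config_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cmp <- compare_strategies(config, mode = mode)
  csv <- file.path(outdir, "comparison.csv")
  write_comparison_csv(cmp, csv)
  manifest <- file.path(outdir, "comparison_manifest.json")
  write_manifest("compare", config, csv, manifest)
  cat(sprintf("Per-patient saving of the testing strategy: EUR %d\n",
              as.integer(round_half_up(-cmp$delta_per_patient))))
  invisible(c(csv, manifest))
}

#' Run the budget-impact analysis and write its reports
#' @inheritParams run_compare_report
#' @return Paths of the written files, invisibly.
#' @export
run_bia_report <- function(config_path = base_case_path(), outdir = ".",
                           mode = "counts") {
  config <- load_validated(config_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bia <- run_budget_impact(config, mode = mode)
  csv <- file.path(outdir, "budget_impact.csv")
  write_bia_csv(bia, csv)
  manifest <- file.path(outdir, "budget_impact_manifest.json")
  write_manifest("bia", config, csv, manifest)
  cat(sprintf("Cumulative %d-year budget impact: EUR %s\n",
              nrow(bia$per_year),
              format(round_half_up(bia$cumulative_difference), big.mark = ",")))
  invisible(c(csv, manifest))
}

#' Run the sensitivity suite and write its reports
#' @inheritParams run_compare_report
#' @return Paths of the written files, invisibly.
#' @export
run_sensitivity_report <- function(config_path = base_case_path(), outdir = ".") {
  config <- load_validated(config_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  suite <- sensitivity_suite(config)
  csv <- file.path(outdir, "sensitivity.csv")
  write_tornado_csv(suite, csv)
  manifest <- file.path(outdir, "sensitivity_manifest.json")
  write_manifest("sensitivity", config, csv, manifest)
  cat(sprintf("Sensitivity entries written: %d\n", nrow(suite)))
  invisible(c(csv, manifest))
}

#' Simulate patients and write records plus summary
#' @inheritParams run_compare_report
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param arm Strategy arm to simulate.
#' @return Paths of the written files, invisibly.
#' @export
run_simulation_report <- function(config_path = base_case_path(), outdir = ".",
                                  n = 10000, seed = 1, arm = "test") {
  config <- load_validated(config_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  records <- simulate_patients(config, arm, n, seed)
  s <- summarize_patients(records, config$cohort_size)
  csv <- file.path(outdir, sprintf("patients_%s.csv", arm))
  write_patient_csv(records, csv)
  summary_csv <- file.path(outdir, sprintf("patients_%s_summary.csv", arm))
  utils::write.csv(data.frame(
    n = s$n, mean_cost_per_patient = fmt_eur(s$mean_cost_per_patient),
    se_mean = fmt_eur(s$se_mean), scaled_total = fmt_eur(s$scaled_total),
    hospitalized_fraction = sprintf("%.4f", s$hospitalized_fraction)
  ), summary_csv, row.names = FALSE)
  manifest <- file.path(outdir, sprintf("patients_%s_manifest.json", arm))
  write_manifest("simulate", config, c(csv, summary_csv), manifest, seed = seed)
  cat(sprintf("Simulated %d %s-arm patients; mean cost EUR %.2f (SE %.2f)\n",
              s$n, arm, s$mean_cost_per_patient, s$se_mean))
  invisible(c(csv, summary_csv, manifest))
}

# Minimal --key value parser for the CLI wrapper.
parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args)) {
      stop_invalid("malformed argument '%s'; expected --key value pairs", key)
    }
    opts[[substring(key, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the subcommands `compare`, `bia`, `sensitivity`, `simulate` and
#' `report` (all of the above). Flags: `--config`, `--outdir`, `--mode`,
#' `--seed`, `--n`, `--arm`. Errors are reported on standard error and turn
#' into a non-zero exit status.
#'
#' @param args Character vector, `c(command, flags...)`; defaults to the
#'   process arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L) stop_invalid("usage: preecon <compare|bia|sensitivity|simulate|report> [--flags]")
    command <- args[1]
    opts <- parse_cli_args(args[-1])
    config <- if (is.null(opts$config)) base_case_path() else opts$config
    outdir <- if (is.null(opts$outdir)) "." else opts$outdir
    mode <- if (is.null(opts$mode)) "counts" else opts$mode
    switch(command,
      compare = run_compare_report(config, outdir, mode),
      bia = run_bia_report(config, outdir, mode),
      sensitivity = run_sensitivity_report(config, outdir),
      simulate = run_simulation_report(
        config, outdir,
        n = if (is.null(opts$n)) 10000 else as.numeric(opts$n),
        seed = if (is.null(opts$seed)) 1 else as.numeric(opts$seed),
        arm = if (is.null(opts$arm)) "test" else opts$arm),
      report = {
        run_compare_report(config, outdir, mode)
        run_bia_report(config, outdir, mode)
        run_sensitivity_report(config, outdir)
      },
      stop_invalid("unknown command '%s'", command)
    )
    0L
  }, error = function(e) {
    message("preecon error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
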