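# Cohort decision tree: branch allocation, strategy costing, comparison.

# Conditional probabilities of the management cascade. Admission inputs come
# from the configured rates (ratio strata for the testing arm; the
# standard-of-care admission rate otherwise); the downstream splits -- birth
# among the admitted, preeclampsia among outpatients, low vs intermediate
# follow-up -- are not published as rates and are derived from the shipped
# branch counts of the same strategy.
probability_parameters <- function(config, strategy) {
  df <- config$strategies[[strategy]]
  bn <- function(id) df$n[df$branch_id == id]
  p_init <- if (strategy == "test") {
    sum(config$strata$prevalence * config$strata$p_hospitalized)
  } else {
    config$probability$no_test$p_admit
  }
  p_pe_admit <- if (strategy == "test") {
    bn("suspected_pe_birth") / (bn("suspected_pe_birth") + bn("intermediate_after_hosp"))
  } else {
    config$probability$no_test$p_pe_given_admit
  }
  amb <- bn("low") + bn("intermediate") + bn("pe_after_ambulatory")
  list(
    p_init_hosp = p_init,
    p_pe_given_admit = p_pe_admit,
    p_pe_ambulatory = bn("pe_after_ambulatory") / amb,
    low_share = bn("low") / (bn("low") + bn("intermediate"))
  )
}

#' Allocate the cohort across management branches
#'
#' In `"counts"` mode the configured branch sizes are returned unchanged (the
#' base case reproduces the published strategy table exactly). In
#' `"probability"` mode expected fractional counts are computed from the
#' admission cascade: per-stratum hospitalization probabilities for the
#' testing arm, the standard-of-care admission rate otherwise, with the
#' remaining conditional splits derived from the configured branch
#' proportions. The initial consultation applies to every woman and is not an
#' allocation branch.
#'
#' @param config A `pe_config`.
#' @param strategy `"no_test"` or `"test"`.
#' @param mode `"counts"` or `"probability"`.
#' @return Data frame with columns `branch_id` and `n`.
#' @export
allocate_cohort <- function(config, strategy, mode = c("counts", "probability")) {
  mode <- match.arg(mode)
  if (!strategy %in% STRATEGIES) stop_invalid("unknown strategy '%s'", strategy)
  df <- config$strategies[[strategy]]
  branch <- df[df$branch_id != "initial_consultation", c("branch_id", "n")]
  if (mode == "counts") {
    rownames(branch) <- NULL
    return(branch)
  }
  p <- probability_parameters(config, strategy)
  N <- config$cohort_size
  admitted <- N * p$p_init_hosp
  amb <- N - admitted
  n <- c(
    low = amb * (1 - p$p_pe_ambulatory) * p$low_share,
    intermediate = amb * (1 - p$p_pe_ambulatory) * (1 - p$low_share),
    intermediate_after_hosp = admitted * (1 - p$p_pe_given_admit),
    suspected_pe_birth = admitted * p$p_pe_given_admit,
    pe_after_ambulatory = amb * p$p_pe_ambulatory
  )
  out <- data.frame(branch_id = branch$branch_id,
                    n = as.numeric(n[branch$branch_id]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate the cost of one management strategy
#'
#' Branch totals are branch size times per-patient cost; the initial
#' consultation is billed for the whole cohort; the testing strategy adds one
#' sFlt-1/PlGF determination per woman (plus any configured extra tests) at
#' the unit cost.
#'
#' @inheritParams allocate_cohort
#' @return A `pe_strategy_result` with branch-level results, the medical cost
#'   total, test cost total, overall total, per-patient cost, and the number
#'   of women hospitalized until birth.
#' @export
strategy_cost <- function(config, strategy, mode = c("counts", "probability")) {
  mode <- match.arg(mode)
  df <- config$strategies[[strategy]]
  alloc <- allocate_cohort(config, strategy, mode)
  n <- c(setNames(alloc$n, alloc$branch_id),
         initial_consultation = as.numeric(config$cohort_size))
  res <- data.frame(
    branch_id = df$branch_id,
    label = df$label,
    n = as.numeric(n[df$branch_id]),
    per_patient = df$per_patient,
    stringsAsFactors = FALSE
  )
  if (any(is.na(res$per_patient))) stop_config("branch without a configured cost")
  res$total_cost <- res$n * res$per_patient
  medical <- sum(res$total_cost)
  n_tests <- if (strategy == "test") config$cohort_size + config$extra_tests else 0
  test_total <- n_tests * config$test_unit_cost
  overall <- medical + test_total
  hosp_birth <- sum(res$n[res$branch_id %in% c("suspected_pe_birth", "pe_after_ambulatory")])
  structure(list(
    strategy = strategy,
    mode = mode,
    cohort_size = config$cohort_size,
    branch_results = res,
    medical_cost_total = medical,
    test_cost_total = test_total,
    overall_total = overall,
    per_patient = overall / config$cohort_size,
    hospitalized_with_birth = hosp_birth
  ), class = "pe_strategy_result")
}

#' @export
print.pe_strategy_result <- function(x, ...) {
  cat(sprintf("<pe_strategy_result> %s (%s mode)\n", x$strategy, x$mode))
  cat(sprintf("  medical costs: EUR %s; test costs: EUR %s\n",
              format(round_half_up(x$medical_cost_total), big.mark = ","),
              format(round_half_up(x$test_cost_total), big.mark = ",")))
  cat(sprintf("  overall: EUR %s (EUR %s per patient); hospitalized until birth: %s\n",
              format(round_half_up(x$overall_total), big.mark = ","),
              format(round_half_up(x$per_patient), big.mark = ","),
              format(round_half_up(x$hospitalized_with_birth))))
  invisible(x)
}

#' Number of women hospitalized until birth
#'
#' Counts the two birth-hospitalization branches (suspected preeclampsia with
#' birth; preeclampsia after ambulatory care), i.e. women hospitalized until
#' delivery rather than initial admissions.
#'
#' @param result A `pe_strategy_result`.
#' @return Count (possibly fractional in probability mode).
#' @export
hospitalized_count <- function(result) {
  stopifnot(inherits(result, "pe_strategy_result"))
  result$hospitalized_with_birth
}

#' Compare two management strategies
#'
#' Evaluates both strategies and reports branch-level and total cost
#' differences, computed as `a` minus `b` (testing minus standard of care by
#' default, so savings appear as negative differences).
#'
#' @inheritParams allocate_cohort
#' @param a,b Strategy names; the comparison is `a - b`.
#' @return A `pe_comparison` with both `pe_strategy_result`s, a per-branch
#'   delta table, `delta_medical`, `delta_total` and `delta_per_patient`.
#' @export
compare_strategies <- function(config, mode = c("counts", "probability"),
                               a = "test", b = "no_test") {
  mode <- match.arg(mode)
  ra <- strategy_cost(config, a, mode)
  rb <- strategy_cost(config, b, mode)
  stopifnot(identical(ra$branch_results$branch_id, rb$branch_results$branch_id))
  per_branch <- data.frame(
    branch_id = ra$branch_results$branch_id,
    delta = ra$branch_results$total_cost - rb$branch_results$total_cost,
    stringsAsFactors = FALSE
  )
  structure(list(
    a = ra, b = rb, mode = mode,
    per_branch_delta = per_branch,
    delta_medical = ra$medical_cost_total - rb$medical_cost_total,
    delta_total = ra$overall_total - rb$overall_total,
    delta_per_patient = (ra$overall_total - rb$overall_total) / config$cohort_size
  ), class = "pe_comparison")
}

#' @export
print.pe_comparison <- function(x, ...) {
  cat(sprintf("<pe_comparison> %s - %s (%s mode)\n", x$a$strategy, x$b$strategy, x$mode))
  cat(sprintf("  delta total: EUR %s; per patient: EUR %s\n",
              format(round_half_up(x$delta_total), big.mark = ","),
              format(round_half_up(x$delta_per_patient))))
  invisible(x)
}

# Per-patient saving of strategy a relative to b (positive = cheaper).
per_patient_saving <- function(config, mode = "counts") {
  -compare_strategies(config, mode = mode)$delta_per_patient
}
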