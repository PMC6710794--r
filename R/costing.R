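# Costing layer: outpatient tariff catalog, inpatient DRG groups, birth costs,
# and bottom-up reconstruction of pathway costs.

SETTINGS <- c("initial", "low", "intermediate")

#' Load the outpatient service catalog
#'
#' One row per tariff item with per-setting costs (EUR) and per-setting
#' `billable_*` flags. An item present in a setting but flagged non-billable
#' (the venipuncture fee in the initial and low settings) is administered --
#' and counted in weekly costs -- but excluded from the printed
#' per-consultation total.
#'
#' @param path CSV path; defaults to the shipped catalog.
#' @return Data frame with columns `service`, `cost_<setting>`,
#'   `billable_<setting>`.
#' @export
load_service_catalog <- function(path = system.file("extdata", "service_catalog.csv",
                                                    package = "preecon", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("service", paste0("cost_", SETTINGS), paste0("billable_", SETTINGS))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("service catalog lacks column(s): %s", paste(miss, collapse = ", "))
  for (s in SETTINGS) {
    cc <- df[[paste0("cost_", s)]]
    if (any(!is.na(cc) & cc < 0)) stop_config("negative service cost in setting '%s'", s)
  }
  df
}

#' Load the inpatient cost groups
#'
#' One row per DRG-style inpatient group with case counts, median/mean length
#' of stay (days) and median/mean episode cost (EUR) from hospital registry
#' records.
#'
#' @param path CSV path; defaults to the shipped groups.
#' @return Data frame with columns `label`, `n`, `los_median_days`,
#'   `los_mean_days`, `cost_median`, `cost_mean`.
#' @export
load_inpatient_groups <- function(path = system.file("extdata", "inpatient_groups.csv",
                                                     package = "preecon", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "n", "los_median_days", "los_mean_days", "cost_median", "cost_mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("inpatient groups lack column(s): %s", paste(miss, collapse = ", "))
  if (any(df$n <= 0)) stop_config("inpatient group sizes must be positive")
  if (any(df$cost_mean < 0) || any(df$los_mean_days < 0)) {
    stop_config("inpatient mean cost and length of stay must be non-negative")
  }
  df
}

#' Per-consultation cost in an outpatient setting
#'
#' Sums the setting's item costs over items flagged billable for that setting.
#' With `include_all = TRUE` every administered item counts (the basis for
#' weekly costs). A `total_override` replaces the itemized sum; the base case
#' uses it for the intermediate setting, whose printed per-consultation total
#' is not reconstructable from its listed items.
#'
#' @param catalog Service catalog data frame.
#' @param setting One of `"initial"`, `"low"`, `"intermediate"`.
#' @param include_all Count administered-but-not-billable items too.
#' @param total_override Optional replacement total (EUR); ignored when
#'   `include_all = TRUE`.
#' @return Cost in EUR.
#' @export
visit_cost <- function(catalog, setting, include_all = FALSE, total_override = NULL) {
  if (!is.character(setting) || length(setting) != 1L || !setting %in% SETTINGS) {
    stop_invalid("unknown outpatient setting '%s'", paste(setting, collapse = ","))
  }
  if (!include_all && !is.null(total_override)) return(as.numeric(total_override))
  if (nrow(catalog) == 0L) stop_invalid("service catalog is empty")
  costs <- catalog[[paste0("cost_", setting)]]
  flags <- catalog[[paste0("billable_", setting)]]
  keep <- !is.na(costs) & (include_all | (!is.na(flags) & flags))
  sum(costs[keep])
}

#' Weekly outpatient cost under a follow-up schedule
#'
#' The cost of one visit (including all administered services, billable or
#' not) multiplied by the number of visits in the follow-up window, divided by
#' its duration in weeks.
#'
#' @inheritParams visit_cost
#' @param visits Number of visits within the follow-up window (>= 1).
#' @param weeks Duration of the window in weeks (> 0).
#' @param total_override Optional per-visit total replacing the itemized sum.
#' @return Cost in EUR per week.
#' @export
weekly_cost <- function(catalog, setting, visits, weeks, total_override = NULL) {
  if (!is.numeric(weeks) || length(weeks) != 1L || weeks <= 0) {
    stop_invalid("follow-up duration must be a positive number of weeks")
  }
  if (!is.numeric(visits) || length(visits) != 1L || visits < 1) {
    stop_invalid("follow-up schedules require at least one visit")
  }
  per_visit <- if (!is.null(total_override)) as.numeric(total_override) else
    visit_cost(catalog, setting, include_all = TRUE)
  per_visit * visits / weeks
}

#' Total inpatient cost across registry groups
#'
#' Expected DRG spend: sum over groups of case count times mean episode cost.
#'
#' @param groups Inpatient group data frame.
#' @return Cost in EUR.
#' @export
inpatient_total <- function(groups) {
  if (is.null(groups) || nrow(groups) == 0L) stop_invalid("inpatient groups are empty")
  sum(groups$n * groups$cost_mean)
}

#' Blended cost of a birth without preeclampsia
#'
#' Mixture of vaginal and C-section DRG costs at the national C-section share.
#'
#' @param csection_share Fraction of births by C-section, in \[0, 1\].
#' @param vaginal_cost Vaginal delivery cost (EUR).
#' @param csection_cost C-section delivery cost (EUR).
#' @return Cost in EUR.
#' @export
blended_birth_cost <- function(csection_share, vaginal_cost, csection_cost) {
  if (!is.numeric(csection_share) || length(csection_share) != 1L ||
      is.na(csection_share) || csection_share < 0 || csection_share > 1) {
    stop_invalid("C-section share must lie in [0, 1]")
  }
  (1 - csection_share) * vaginal_cost + csection_share * csection_cost
}

# Weekly cost for a named schedule of the configuration.
config_weekly_cost <- function(config, setting) {
  sched <- config$outpatient$schedules[[setting]]
  if (is.null(sched)) stop_config("no outpatient schedule for setting '%s'", setting)
  override <- if (setting == "intermediate") config$outpatient$intermediate_total_override else NULL
  weekly_cost(config$outpatient$catalog, setting, sched$visits, sched$weeks, override)
}

#' Bottom-up per-patient cost of a management branch
#'
#' Recomposes a branch's per-patient cost from the tariff catalog, follow-up
#' schedules, inpatient groups and birth-cost model, as an independent
#' alternative to the per-patient costs implied by the branch totals:
#' weeks of follow-up times the weekly cost, plus the mean inpatient episode
#' cost where the pathway includes an admission, plus a delivery cost (blended
#' without preeclampsia; registry-weighted vaginal/C-section mix with
#' preeclampsia). The two outpatient branches reconcile with the implied costs
#' within a fraction of a percent; the preeclampsia branches do not (their
#' implied costs embed partial episodes) and are reported as-is.
#'
#' @param config A `pe_config`.
#' @param branch_id One of the model's branch identifiers.
#' @param strategy `"no_test"` or `"test"` (sets the default weeks of
#'   follow-up after an admission without birth: 2 and 4 respectively).
#' @param weeks_outpatient Weeks of low/intermediate follow-up (default 8).
#' @param weeks_after_discharge Weeks of intermediate follow-up after a
#'   discharge; `NULL` uses the strategy default.
#' @return Per-patient cost in EUR.
#' @export
bottom_up_branch_cost <- function(config, branch_id, strategy = "test",
                                  weeks_outpatient = 8, weeks_after_discharge = NULL) {
  if (!branch_id %in% BRANCH_IDS) stop_invalid("unknown branch_id '%s'", branch_id)
  if (!strategy %in% STRATEGIES) stop_invalid("unknown strategy '%s'", strategy)
  if (is.null(weeks_after_discharge)) {
    weeks_after_discharge <- if (strategy == "test") 4 else 2
  }
  groups <- config$inpatient$groups
  stay_mean <- groups$cost_mean[groups$label == "suspected_no_birth"]
  pe_birth <- {
    g <- groups[groups$label %in% c("vaginal_with_pe", "csection_with_pe"), ]
    sum(g$n * g$cost_mean) / sum(g$n)
  }
  blended <- config$birth$blended_cost_no_pe
  switch(branch_id,
    initial_consultation = visit_cost(config$outpatient$catalog, "initial", include_all = TRUE),
    low = weeks_outpatient * config_weekly_cost(config, "low") + blended,
    intermediate = weeks_outpatient * config_weekly_cost(config, "intermediate") + blended,
    intermediate_after_hosp = stay_mean +
      weeks_after_discharge * config_weekly_cost(config, "intermediate") + blended,
    suspected_pe_birth = stay_mean + pe_birth,
    pe_after_ambulatory = weeks_outpatient / 2 * config_weekly_cost(config, "intermediate") + pe_birth
  )
}
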