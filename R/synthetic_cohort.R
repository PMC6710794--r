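# Patient-level synthetic data: microsimulation of the management cascade,
# parameter recovery, and a synthetic inpatient registry.

#' Simulate individual patients through the management cascade
#'
#' Draws one record per simulated pregnancy following the same conditional
#' structure the deterministic tree uses in probability mode: ratio stratum
#' from the configured prevalences (testing arm only), initial hospitalization
#' per stratum (testing) or at the standard-of-care admission rate (no-test),
#' preeclampsia conditionals and the low/intermediate split from the
#' configured branch proportions, and delivery mode at the configured
#' C-section share. In the ratio <= 38 stratum an admission is equated with a
#' severe blood-pressure reading (> 160/110 mmHg), the model's only admission
#' trigger there. Costs are assigned deterministically from the branch
#' per-patient costs; `cost_total` adds the initial consultation and, in the
#' testing arm, the test cost.
#'
#' @param config A `pe_config`.
#' @param arm `"no_test"` or `"test"`.
#' @param n Number of patients to simulate (> 0).
#' @param seed Integer seed; identical inputs give identical records.
#' @return Data frame with one row per patient: `patient_id`, `stratum`,
#'   `severe_bp`, `initially_hospitalized`, `developed_pe`, `birth_mode`,
#'   `branch_id`, `pathway_cost`, `cost_total`.
#' @export
simulate_patients <- function(config, arm, n, seed) {
  if (!arm %in% STRATEGIES) stop_invalid("unknown arm '%s'", arm)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_invalid("n must be >= 1")
  n <- as.integer(n)
  p <- probability_parameters(config, arm)
  df <- config$strategies[[arm]]
  pp <- setNames(df$per_patient, df$branch_id)
  overhead <- pp[["initial_consultation"]] +
    if (arm == "test") config$test_unit_cost else 0

  with_local_seed(seed, {
    if (arm == "test") {
      stratum <- sample(config$strata$label, n, replace = TRUE,
                        prob = config$strata$prevalence)
      p_h <- config$strata$p_hospitalized[match(stratum, config$strata$label)]
      hosp <- runif(n) < p_h
      severe_bp <- stratum == "ratio_le_38" & hosp
    } else {
      stratum <- rep(NA_character_, n)
      hosp <- runif(n) < p$p_init_hosp
      severe_bp <- rep(NA, n)
    }
    pe_admit <- hosp & runif(n) < p$p_pe_given_admit
    pe_amb <- !hosp & runif(n) < p$p_pe_ambulatory
    go_low <- runif(n) < p$low_share
    branch <- ifelse(hosp,
                     ifelse(pe_admit, "suspected_pe_birth", "intermediate_after_hosp"),
                     ifelse(pe_amb, "pe_after_ambulatory",
                            ifelse(go_low, "low", "intermediate")))
    birth_mode <- ifelse(runif(n) < config$birth$csection_share, "csection", "vaginal")
    data.frame(
      patient_id = sprintf("P%07d", seq_len(n)),
      stratum = stratum,
      severe_bp = severe_bp,
      initially_hospitalized = hosp,
      developed_pe = branch %in% c("suspected_pe_birth", "pe_after_ambulatory"),
      birth_mode = birth_mode,
      branch_id = branch,
      pathway_cost = as.numeric(pp[branch]),
      cost_total = as.numeric(pp[branch]) + overhead,
      stringsAsFactors = FALSE
    )
  })
}

#' Summarize simulated patient records
#'
#' @param records Data frame from [simulate_patients()].
#' @param cohort_scale Cohort size to which the mean cost is scaled.
#' @return A `pe_sim_summary`: `n`, `mean_cost_per_patient`, `se_mean` (`NA`
#'   for a single record), `scaled_total`, `hospitalized_fraction` (initial
#'   admissions), `stratum_counts`.
#' @export
summarize_patients <- function(records, cohort_scale) {
  if (is.null(records) || nrow(records) == 0L) stop_invalid("no patient records to summarize")
  n <- nrow(records)
  m <- mean(records$cost_total)
  se <- if (n > 1L) stats::sd(records$cost_total) / sqrt(n) else NA_real_
  structure(list(
    n = n,
    mean_cost_per_patient = m,
    se_mean = se,
    scaled_total = m * cohort_scale,
    hospitalized_fraction = mean(records$initially_hospitalized),
    stratum_counts = table(records$stratum, useNA = "no")
  ), class = "pe_sim_summary")
}

#' @export
print.pe_sim_summary <- function(x, ...) {
  cat(sprintf("<pe_sim_summary> n = %d\n", x$n))
  cat(sprintf("  mean cost/patient: EUR %.2f (SE %.2f); initially hospitalized: %.1f%%\n",
              x$mean_cost_per_patient, x$se_mean, 100 * x$hospitalized_fraction))
  invisible(x)
}

# Log-normal parameters from a (median, mean) pair: the median fixes meanlog,
# the mean/median ratio fixes sdlog. Requires mean >= median.
lognormal_from_median_mean <- function(med, mn, what) {
  if (mn < med) {
    stop_config("%s: mean (%.2f) below median (%.2f) is impossible for a log-normal", what, mn, med)
  }
  list(meanlog = log(med), sdlog = sqrt(2 * log(mn / med)))
}

#' Simulate an inpatient cost registry
#'
#' Emulates registry records consistent with the configured inpatient groups:
#' group membership proportional to the group case counts; length of stay and
#' episode cost drawn from log-normal distributions parameterized so the
#' sample median and mean converge to each group's recorded median and mean.
#'
#' @param groups Inpatient group data frame (see [load_inpatient_groups()]).
#' @param n Number of registry records (> 0).
#' @param seed Integer seed.
#' @return Data frame `group`, `los_days`, `cost`.
#' @export
simulate_registry <- function(groups, n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_invalid("n must be >= 1")
  n <- as.integer(n)
  pars <- lapply(seq_len(nrow(groups)), function(i) {
    list(
      cost = lognormal_from_median_mean(groups$cost_median[i], groups$cost_mean[i],
                                        paste0(groups$label[i], " cost")),
      los = lognormal_from_median_mean(groups$los_median_days[i], groups$los_mean_days[i],
                                       paste0(groups$label[i], " length of stay"))
    )
  })
  names(pars) <- groups$label
  with_local_seed(seed, {
    grp <- sample(groups$label, n, replace = TRUE, prob = groups$n / sum(groups$n))
    los <- numeric(n)
    cost <- numeric(n)
    for (g in groups$label) {
      idx <- which(grp == g)
      if (!length(idx)) next
      los[idx] <- rlnorm(length(idx), pars[[g]]$los$meanlog, pars[[g]]$los$sdlog)
      cost[idx] <- rlnorm(length(idx), pars[[g]]$cost$meanlog, pars[[g]]$cost$sdlog)
    }
    data.frame(group = grp, los_days = los, cost = cost, stringsAsFactors = FALSE)
  })
}

binom_ci <- function(k, n) {
  if (n == 0L) return(c(NA_real_, NA_real_, NA_real_))
  ci <- stats::binom.test(k, n)$conf.int
  c(k / n, ci[1], ci[2])
}

#' Recover generating parameters from simulated records
#'
#' Maximum-likelihood estimates (sample proportions) of the stratum
#' prevalences and per-stratum hospitalization probabilities, with exact
#' binomial 95% confidence intervals. Strata without observations are
#' reported with `NA` estimates.
#'
#' @param records Testing-arm records from [simulate_patients()].
#' @return Data frame `parameter`, `estimate`, `conf_low`, `conf_high`,
#'   `n_obs`.
#' @export
recover_parameters <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop_invalid("no records")
  if (all(is.na(records$stratum))) {
    stop_invalid("parameter recovery requires testing-arm records with strata")
  }
  n <- nrow(records)
  rows <- list()
  for (lab in STRATUM_LABELS) {
    in_s <- records$stratum == lab
    k <- sum(in_s)
    ci <- binom_ci(k, n)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("prevalence.", lab), estimate = ci[1],
      conf_low = ci[2], conf_high = ci[3], n_obs = n, stringsAsFactors = FALSE)
    kh <- sum(records$initially_hospitalized[in_s])
    cih <- binom_ci(kh, k)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("p_hospitalized.", lab), estimate = cih[1],
      conf_low = cih[2], conf_high = cih[3], n_obs = k, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
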