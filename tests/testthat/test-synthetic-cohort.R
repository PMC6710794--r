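test_that("simulation is reproducible and structurally valid", {
  cfg <- base_cfg()
  a <- simulate_patients(cfg, "test", 500, seed = 42)
  b <- simulate_patients(cfg, "test", 500, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_patients(cfg, "test", 500, seed = 43)))

  one <- simulate_patients(cfg, "test", 1, seed = 7)
  expect_identical(nrow(one), 1L)
  expect_true(one$branch_id %in% c("low", "intermediate", "intermediate_after_hosp",
                                   "suspected_pe_birth", "pe_after_ambulatory"))

  expect_error(simulate_patients(cfg, "test", 0, seed = 1),
               class = "pe_invalid_parameter")
  expect_error(simulate_patients(cfg, "soc", 10, seed = 1),
               class = "pe_invalid_parameter")
})

test_that("records respect the severe blood-pressure admission rule and costs", {
  cfg <- base_cfg()
  rec <- simulate_patients(cfg, "test", 20000, seed = 11)
  le38 <- rec[rec$stratum == "ratio_le_38", ]
  expect_true(all(le38$initially_hospitalized[le38$severe_bp]))
  expect_identical(le38$severe_bp, le38$initially_hospitalized)

  # pathway cost equals the branch's configured per-patient cost; the total
  # adds the initial consultation and one test
  df <- cfg$strategies$test
  pp <- setNames(df$per_patient, df$branch_id)
  expect_equal(rec$pathway_cost, unname(pp[rec$branch_id]))
  expect_equal(rec$cost_total - rec$pathway_cost,
               rep(pp[["initial_consultation"]] + cfg$test_unit_cost, nrow(rec)))

  # preeclampsia flag is the birth-hospitalization indicator
  expect_identical(rec$developed_pe,
                   rec$branch_id %in% c("suspected_pe_birth", "pe_after_ambulatory"))
})

test_that("simulated frequencies converge to the configured probabilities", {
  cfg <- base_cfg()
  n <- 100000
  rec <- simulate_patients(cfg, "test", n, seed = 5)
  for (i in seq_len(nrow(cfg$strata))) {
    p <- cfg$strata$prevalence[i]
    obs <- mean(rec$stratum == cfg$strata$label[i])
    expect_lt(abs(obs - p), 3 * binom_se(p, n),
              label = paste("prevalence", cfg$strata$label[i]))
  }
  nt <- simulate_patients(cfg, "no_test", n, seed = 6)
  expect_lt(abs(mean(nt$initially_hospitalized) - 0.36), 3 * binom_se(0.36, n))
})

test_that("summaries report mean, spread and admissions", {
  cfg <- base_cfg()
  rec <- simulate_patients(cfg, "test", 5000, seed = 3)
  s <- summarize_patients(rec, cfg$cohort_size)
  expect_equal(s$n, 5000)
  expect_equal(s$se_mean, sd(rec$cost_total) / sqrt(5000))
  expect_equal(s$scaled_total, s$mean_cost_per_patient * 6084)
  expect_equal(sum(s$stratum_counts), 5000)

  single <- summarize_patients(rec[1, ], 6084)
  expect_true(is.na(single$se_mean))
  flat <- rec[rec$branch_id == "low", ]
  expect_equal(summarize_patients(flat, 6084)$se_mean, 0)
  expect_error(summarize_patients(rec[0, ], 6084), class = "pe_invalid_parameter")
})

test_that("the synthetic registry matches the recorded group moments", {
  groups <- load_inpatient_groups()
  expect_identical(simulate_registry(groups, 10, seed = 9),
                   simulate_registry(groups, 10, seed = 9))
  reg <- simulate_registry(groups, 100000, seed = 3)
  shares <- groups$n / sum(groups$n)
  for (i in seq_len(nrow(groups))) {
    g <- groups$label[i]
    expect_lt(abs(mean(reg$group == g) - shares[i]), 3 * binom_se(shares[i], 100000))
    sub <- reg[reg$group == g, ]
    expect_lt(abs(mean(sub$cost) - groups$cost_mean[i]) / groups$cost_mean[i], 0.02,
              label = paste(g, "mean cost"))
    expect_lt(abs(stats::median(sub$cost) - groups$cost_median[i]) / groups$cost_median[i],
              0.03, label = paste(g, "median cost"))
    expect_lt(abs(mean(sub$los_days) - groups$los_mean_days[i]) / groups$los_mean_days[i],
              0.03, label = paste(g, "mean length of stay"))
  }
  bad <- groups
  bad$cost_mean[1] <- bad$cost_median[1] - 1
  expect_error(simulate_registry(bad, 10, seed = 1), class = "pe_config_error")
})

test_that("parameter recovery brackets the generating values", {
  cfg <- base_cfg()
  rec <- simulate_patients(cfg, "test", 100000, seed = 21)
  est <- recover_parameters(rec)
  truth <- c(setNames(cfg$strata$prevalence, paste0("prevalence.", cfg$strata$label)),
             setNames(cfg$strata$p_hospitalized,
                      paste0("p_hospitalized.", cfg$strata$label)))
  # each estimate within four binomial standard errors of its generating value
  # (a joint all-CIs-cover check at one seed would fail a quarter of the time
  # by construction even for a perfect estimator)
  inside <- 0L
  for (p in names(truth)) {
    row <- est[est$parameter == p, ]
    expect_lt(abs(row$estimate - truth[[p]]),
              4 * binom_se(truth[[p]], row$n_obs), label = p)
    inside <- inside + (row$conf_low <= truth[[p]] && truth[[p]] <= row$conf_high)
  }
  expect_gte(inside, 4L)
  expect_error(recover_parameters(simulate_patients(cfg, "no_test", 10, seed = 1)),
               class = "pe_invalid_parameter")
})

test_that("confidence intervals achieve nominal coverage across replicates", {
  cfg <- base_cfg()
  truth <- c(setNames(cfg$strata$prevalence, paste0("prevalence.", cfg$strata$label)),
             setNames(cfg$strata$p_hospitalized,
                      paste0("p_hospitalized.", cfg$strata$label)))
  reps <- 50
  hits <- setNames(numeric(length(truth)), names(truth))
  for (r in seq_len(reps)) {
    est <- recover_parameters(simulate_patients(cfg, "test", 20000, seed = 1000 + r))
    for (p in names(truth)) {
      row <- est[est$parameter == p, ]
      hits[p] <- hits[p] + (row$conf_low <= truth[[p]] && truth[[p]] <= row$conf_high)
    }
  }
  # verify the >= 93% coverage claim as a one-sided hypothesis test: reject
  # only if the observed hit count is significantly below 93% (alpha 0.001),
  # i.e. the simulation must not provide evidence against nominal coverage
  min_hits <- stats::qbinom(0.001, reps, 0.93)
  expect_true(all(hits >= min_hits),
              info = paste("coverage:", paste(hits / reps, collapse = ", ")))
})
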