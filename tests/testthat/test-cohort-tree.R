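test_that("counts mode returns the configured branch allocation", {
  alloc <- allocate_cohort(base_cfg(), "test", "counts")
  expect_equal(setNames(alloc$n, alloc$branch_id),
               c(low = 2185, intermediate = 2498, intermediate_after_hosp = 580,
                 suspected_pe_birth = 380, pe_after_ambulatory = 442))
})

test_that("probability mode reproduces the admission cascade", {
  cfg <- base_cfg()
  alloc <- allocate_cohort(cfg, "test", "probability")
  admitted <- sum(alloc$n[alloc$branch_id %in%
                            c("intermediate_after_hosp", "suspected_pe_birth")])
  # oracle: 6084 * (0.76*0.02 + 0.11*0.55 + 0.13*0.65) = 974.6568
  expect_equal(admitted, 6084 * 0.1602, tolerance = 1e-9)
  nt <- allocate_cohort(cfg, "no_test", "probability")
  admitted_nt <- sum(nt$n[nt$branch_id %in%
                            c("intermediate_after_hosp", "suspected_pe_birth")])
  expect_equal(admitted_nt, 6084 * 0.36, tolerance = 1e-9)
  # standard of care: 27% of admitted stay hospitalized until birth
  expect_equal(nt$n[nt$branch_id == "suspected_pe_birth"],
               6084 * 0.36 * 0.27, tolerance = 1e-9)

  # degenerate cohort allocates nobody
  tiny <- config_set(cfg, "cohort.births_per_year", 1)
  expect_identical(tiny$cohort_size, 0L)
  expect_equal(allocate_cohort(tiny, "test", "probability")$n, rep(0, 5))
})

test_that("cohort conservation holds within one woman in every mode", {
  cfg <- base_cfg()
  for (strategy in c("no_test", "test")) {
    for (mode in c("counts", "probability")) {
      alloc <- allocate_cohort(cfg, strategy, mode)
      expect_lte(abs(sum(alloc$n) - cfg$cohort_size), 1,
                 label = sprintf("conservation %s/%s", strategy, mode))
    }
  }
})

test_that("strategy costs reproduce the base-case totals", {
  cfg <- base_cfg()
  nt <- strategy_cost(cfg, "no_test")
  t <- strategy_cost(cfg, "test")
  expect_equal(nt$overall_total, 66469362, tolerance = 1e-9)
  expect_equal(nt$test_cost_total, 0)
  expect_equal(t$medical_cost_total, 63506433, tolerance = 1e-9)
  expect_equal(t$test_cost_total, 6084 * 140.80)
  expect_equal(t$overall_total, t$medical_cost_total + t$test_cost_total)
  expect_equal(nt$per_patient, 66469362 / 6084)

  # degenerate: all costs zero
  z <- cfg
  for (s in names(z$strategies)) {
    for (col in c("per_patient", "total_cost", "comp_outpatient",
                  "comp_hospitalization", "comp_birth")) {
      z$strategies[[s]][[col]] <- 0
    }
  }
  z$test_unit_cost <- 0
  expect_equal(strategy_cost(z, "test")$overall_total, 0)
})

test_that("accounting identity holds at cent precision", {
  for (strategy in c("no_test", "test")) {
    for (mode in c("counts", "probability")) {
      r <- strategy_cost(base_cfg(), strategy, mode)
      expect_equal(r$overall_total,
                   sum(r$branch_results$n * r$branch_results$per_patient) +
                     r$test_cost_total,
                   tolerance = 1e-10)
      expect_lt(abs(r$overall_total - (r$medical_cost_total + r$test_cost_total)), 0.01)
    }
  }
})

test_that("strategy comparison yields the published savings", {
  cfg <- base_cfg()
  cmp <- compare_strategies(cfg)
  expect_equal(cmp$delta_total, -2106301.8, tolerance = 1e-8)
  expect_equal(cmp$delta_medical, -2962929, tolerance = 1e-9)
  expect_identical(round(cmp$delta_per_patient), -346)

  # a free test turns the difference into the pure medical saving
  free <- config_set(cfg, "costs.test_unit_cost", 0)
  expect_equal(compare_strategies(free)$delta_total, -2962929, tolerance = 1e-9)

  # identical strategies compare to zero
  same <- config_set(cfg, "costs.test_unit_cost", 0)
  same$strategies$test <- same$strategies$no_test
  cmp0 <- compare_strategies(same)
  expect_equal(cmp0$delta_total, 0)
  expect_equal(cmp0$per_branch_delta$delta, rep(0, 6))
})

test_that("comparison is antisymmetric under strategy swap", {
  cfg <- base_cfg()
  ab <- compare_strategies(cfg, a = "test", b = "no_test")
  ba <- compare_strategies(cfg, a = "no_test", b = "test")
  expect_equal(ab$delta_total, -ba$delta_total)
  expect_equal(ab$delta_per_patient, -ba$delta_per_patient)
  expect_equal(ab$per_branch_delta$delta, -ba$per_branch_delta$delta)
})

test_that("women hospitalized until birth match the branch table", {
  cfg <- base_cfg()
  expect_equal(hospitalized_count(strategy_cost(cfg, "no_test")), 1160)
  expect_equal(hospitalized_count(strategy_cost(cfg, "test")), 822)
  z <- cfg
  z$strategies$test$n <- 0
  expect_equal(hospitalized_count(strategy_cost(z, "test")), 0)
})

test_that("per-patient difference is monotone in test cost and low-stratum admissions", {
  cfg <- base_cfg()
  deltas <- vapply(c(100, 140.80, 200), function(uc) {
    compare_strategies(config_set(cfg, "costs.test_unit_cost", uc))$delta_per_patient
  }, numeric(1))
  expect_true(all(diff(deltas) > 0))

  # hospitalized pathways cost more than outpatient ones, so raising the
  # rule-out stratum's admission probability erodes the saving
  deltas_p <- vapply(c(0.02, 0.04, 0.08), function(p) {
    compare_strategies(config_set(cfg, "strata.ratio_le_38.p_hospitalized", p),
                       mode = "probability")$delta_per_patient
  }, numeric(1))
  expect_true(all(diff(deltas_p) > 0))
})
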