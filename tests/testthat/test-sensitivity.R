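spec_of <- function(path, modifier, mode = "relative", label = "x") {
  list(label = label, parameter_path = path, modifier = modifier, mode = mode)
}

test_that("modifiers scale or replace exactly one parameter, purely", {
  cfg <- base_cfg()
  up <- apply_modifier(cfg, spec_of("costs.test_unit_cost", 0.20))
  expect_equal(up$test_unit_cost, 168.96)
  expect_equal(cfg$test_unit_cost, 140.80)

  dbl <- apply_modifier(cfg, spec_of("strata.ratio_le_38.p_hospitalized", 1.00))
  expect_equal(config_get(dbl, "strata.ratio_le_38.p_hospitalized"), 0.04)

  abs_set <- apply_modifier(cfg, spec_of("costs.test_unit_cost", 99, mode = "absolute"))
  expect_equal(abs_set$test_unit_cost, 99)

  # identity and inverse
  same <- apply_modifier(cfg, spec_of("costs.test_unit_cost", 0))
  expect_equal(same$test_unit_cost, cfg$test_unit_cost)
  x <- 0.37
  back <- apply_modifier(apply_modifier(cfg, spec_of("costs.test_unit_cost", x)),
                         spec_of("costs.test_unit_cost", -x / (1 + x)))
  expect_equal(back$test_unit_cost, cfg$test_unit_cost, tolerance = 1e-9)

  expect_error(apply_modifier(cfg, spec_of("no.such", 0.2)), class = "pe_config_error")
  expect_error(apply_modifier(cfg, spec_of("costs.test_unit_cost", -1)),
               class = "pe_config_error")
})

test_that("component modifiers rescale branch cost components consistently", {
  cfg <- base_cfg()
  up <- apply_modifier(cfg, spec_of("costs.hospitalization", 0.20))
  for (s in names(up$strategies)) {
    expect_equal(up$strategies[[s]]$comp_hospitalization,
                 1.2 * cfg$strategies[[s]]$comp_hospitalization)
    expect_equal(up$strategies[[s]]$per_patient,
                 up$strategies[[s]]$comp_outpatient +
                   up$strategies[[s]]$comp_hospitalization +
                   up$strategies[[s]]$comp_birth)
  }
})

test_that("one-way analysis records savings against the matching-mode base", {
  cfg <- base_cfg()
  entries <- one_way(cfg, list(
    spec_of("costs.test_unit_cost", 0.20, label = "up"),
    spec_of("costs.test_unit_cost", -0.20, label = "down")
  ))
  # oracle: base saving 346.2035 shifted by 0.2 x 140.80 = 28.16
  expect_equal(entries$per_patient_saving[entries$label == "up"], 318.0435,
               tolerance = 1e-4)
  expect_equal(entries$per_patient_saving[entries$label == "down"], 374.3635,
               tolerance = 1e-4)
  expect_equal(one_way(cfg, list())$label, character(0))

  # deterministic ordering: descending |delta|, ties broken by label
  suite <- one_way(cfg)
  expect_equal(order(-abs(suite$delta_vs_base), suite$label), seq_len(nrow(suite)))
  expect_identical(suite, one_way(cfg))
})

test_that("directional findings hold across the configured one-way set", {
  cfg <- base_cfg()
  suite <- one_way(cfg)
  base_counts <- -compare_strategies(cfg)$delta_per_patient
  base_prob <- -compare_strategies(cfg, mode = "probability")$delta_per_patient

  hosp_up <- suite[suite$label == "Hospitalization costs +20%", ]
  expect_gt(hosp_up$per_patient_saving, base_counts)

  le38_up <- suite[suite$label == "P(hospitalized | ratio <=38) +100%", ]
  expect_lt(le38_up$per_patient_saving, base_prob)

  # the test-cost bar is the shortest in the tornado
  bars <- tornado_summary(suite)
  expect_identical(bars$parameter_path[nrow(bars)], "costs.test_unit_cost")
})

test_that("retest scenarios reprice testing without shifting management", {
  cfg <- base_cfg()
  all_once <- run_scenario(cfg, list(name = "retest", label = "all",
                                     retest_fraction = 1, retest_population = "all",
                                     tests_per_retested_patient = 1))
  # oracle: 346.2035 - 140.80 = 205.4035
  expect_equal(all_once$per_patient_saving, 205.4035, tolerance = 1e-4)

  none <- run_scenario(cfg, list(name = "retest", label = "none",
                                 retest_fraction = 0, retest_population = "all",
                                 tests_per_retested_patient = 1))
  expect_equal(none$per_patient_saving, 346.2035, tolerance = 1e-4)

  int4 <- run_scenario(cfg, list(name = "retest", label = "int4",
                                 retest_fraction = 1,
                                 retest_population = "intermediate_4x",
                                 tests_per_retested_patient = 4))
  # oracle: 346.2035 - 4 x 2498 x 140.80 / 6084 = 114.98
  expect_equal(int4$per_patient_saving, 346.2035 - 4 * 2498 * 140.80 / 6084,
               tolerance = 1e-6)

  expect_error(run_scenario(cfg, list(name = "retest", retest_fraction = 2,
                                      retest_population = "all",
                                      tests_per_retested_patient = 1)),
               class = "pe_config_error")
  expect_error(run_scenario(cfg, list(name = "mystery")), class = "pe_config_error")
})

test_that("the full suite covers the configured scenario set", {
  suite <- sensitivity_suite(base_cfg())
  expect_gte(nrow(suite), 8)
  expect_true("Birth costs excluded" %in% suite$label)
  expect_identical(sum(suite$kind == "scenario"), 4L)
  # excluding birth costs keeps the testing strategy cost saving
  expect_gt(suite$per_patient_saving[suite$label == "Birth costs excluded"], 0)
})
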