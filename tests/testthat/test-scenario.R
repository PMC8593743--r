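test_that("the bundled base case carries the reference data", {
  cfg <- base_cfg
  expect_length(cfg$drugs, 8)
  expect_equal(cfg$drugs$risankizumab$p_induction, 0.892)
  expect_equal(cfg$drugs$risankizumab$p_induction_ci, c(0.869, 0.913))
  expect_equal(cfg$drugs$etanercept$cost_per_dispense, 1026)
  expect_equal(cfg$drugs$tildrakizumab$cost_per_dispense, 3246)
  expect_equal(cfg$utilities$u_controlled, 0.89)
  expect_equal(cfg$utilities$u_uncontrolled, 0.64)
  expect_equal(cfg$bsc$cyclosporine_maintenance, 5644)
  expect_equal(cfg$timeline$horizon_weeks, 96)
  expect_no_error(validate_scenario(cfg))
})

test_that("scenario files round-trip through JSON and YAML", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_scenario(base_cfg, tmp)
  again <- load_scenario(tmp)
  expect_equal(scenario_to_list(again), scenario_to_list(base_cfg))
  expect_equal(evaluate_arm(base_strategies$tildrakizumab, again)$total_cost,
               evaluate_arm(base_strategies$tildrakizumab, base_cfg)$total_cost)
  skip_if_not_installed("yaml")
  tmpy <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(base_cfg, tmpy)
  expect_equal(scenario_to_list(load_scenario(tmpy)), scenario_to_list(base_cfg))
})

test_that("validation rejects malformed scenarios with named fields", {
  expect_error(utility_set(0.9, 0.6), "u_controlled")
  bad <- base_cfg
  bad$utilities$u_controlled <- 0.5   # below u_uncontrolled
  err <- tryCatch(validate_scenario(bad), error = identity)
  expect_s3_class(err, "psor_validation_error")
  expect_match(conditionMessage(err), "utilities")

  bad2 <- base_cfg
  bad2$drugs$adalimumab$p_induction_ci <- c(0.8, 0.9)  # point outside CI
  err2 <- tryCatch(validate_scenario(bad2), error = identity)
  expect_s3_class(err2, "psor_validation_error")
  expect_match(conditionMessage(err2), "adalimumab")

  expect_error(load_scenario("no/such/file.json"), "not found")
  expect_error(monitoring_costs(-1, 0, 0, 0), ">= 0")
  expect_error(drug_profile("x", -5, dosing_schedule(0, 4), .5, c(.4, .6),
                            .5, c(.4, .6)), "cost_per_dispense")
})

test_that("strategies follow the sequencing rules and end after three lines", {
  s <- base_strategies
  expect_length(s, 8)
  expect_equal(s$adalimumab$lines, c("adalimumab", "risankizumab", "ixekizumab"))
  expect_equal(s$risankizumab$lines, c("risankizumab", "ixekizumab", "guselkumab"))
  expect_equal(s$ixekizumab$lines, c("ixekizumab", "risankizumab", "guselkumab"))
  alt <- build_strategies(base_cfg, rule = "alternative")
  expect_length(alt, 8)
  expect_equal(alt$etanercept$lines, c("etanercept", "guselkumab", "ixekizumab"))
  expect_equal(alt$guselkumab$lines, c("guselkumab", "ixekizumab", "risankizumab"))
  expect_equal(alt$ixekizumab$lines, c("ixekizumab", "guselkumab", "risankizumab"))
  for (st in c(s, alt)) expect_length(unique(st$lines), 3)
  expect_error(build_strategies(base_cfg, rule = "bogus"), "sequencing_rule")
  expect_error(strategy("x", c("a", "b", "a")), "twice")
})
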