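## experiment runners, verdict plumbing and report serialization; all runs
## here use the coarse-step configuration (same 16.6 h of simulated time)

test_that("wild-type experiment recovers the central AG domain and
           pre-gate silence", {
  rep <- cached("exp_wt", run_wildtype(coarse_config()))
  expect_true(all(rep$verdicts))
  expect_identical(unname(rep$comparisons[["ag_peak_cell"]]), 8)
  expect_gte(rep$comparisons[["ag_silence_end_h"]], 5)
  expect_identical(unname(rep$comparisons[["max_pre_gate_ag"]]), 0)
  expect_gt(rep$comparisons[["final_center_ag"]], 0)
})

test_that("narrow boundary broadens the AG domain but keeps its form and
           symmetry", {
  rep <- cached("exp_narrow", run_narrow_boundary(coarse_config()))
  expect_true(all(rep$verdicts))
  expect_gt(rep$comparisons[["ag_width_narrow"]],
            rep$comparisons[["ag_width_wide"]])
  expect_lt(rep$comparisons[["symmetry_error_narrow"]], 1e-10)
})

test_that("coupling sweeps and random couplings leave the final pattern
           unchanged", {
  rep <- cached("exp_eps",
                run_epsilon_experiments(values = c(0, 10), seed = 3L,
                                        config = coarse_config()))
  expect_true(all(rep$verdicts))
  expect_lt(rep$comparisons[["max_distance"]], 1e-10)
  expect_setequal(rep$tables$distances$variant,
                  c("eps_0", "eps_10", "random_time", "random_per_cell"))
})

test_that("epsilon experiments are reproducible given the seed", {
  a <- run_epsilon_experiments(values = 5, random_mode = TRUE, seed = 9L,
                               config = coarse_config())
  b <- run_epsilon_experiments(values = 5, random_mode = TRUE, seed = 9L,
                               config = coarse_config())
  expect_identical(a$comparisons, b$comparisons)
  expect_identical(a$configs$random_time$epsilon_schedule,
                   b$configs$random_time$epsilon_schedule)
})

test_that("TFL1 knockout floods the centre with AG and starves edge AP1", {
  rep <- cached("exp_ko", run_tfl1_knockout(coarse_config()))
  expect_true(all(rep$verdicts))
  expect_gt(rep$comparisons[["ko_center_ag"]],
            rep$comparisons[["wt_center_ag"]])
  expect_lt(rep$comparisons[["ko_edge_ap1T"]],
            rep$comparisons[["wt_edge_ap1T"]])
  expect_gt(rep$comparisons[["wt_min_tfl1"]], 0)
})

test_that("WUS-driven exclusion preserves the zone layout", {
  rep <- cached("exp_swap", run_wus_exclusion_variant(coarse_config()))
  expect_true(all(rep$verdicts))
  expect_equal(unname(rep$comparisons[["label_mismatches"]]), 0)
})

test_that("AG-driven exclusion is the identity variant of the wild type", {
  cfg <- coarse_config()
  a <- simulate_abc(cfg)
  b <- simulate_abc(run_config(
    grid = cfg$grid, kinetics = cfg$kinetics, wus = cfg$wus,
    boundary = cfg$boundary,
    options = model_options(exclusion_driver = "AG"),
    dt = cfg$dt, n_steps = cfg$n_steps, sample_every = cfg$sample_every))
  expect_identical(a$fields, b$fields)
})

test_that("the +/-10% robustness scan books one stable row per rate
           constant", {
  rep <- cached("exp_rob",
                run_robustness_scan("pm10", seed = 5L,
                                    config = coarse_config()))
  scan <- rep$tables$scan
  expect_identical(nrow(scan), 16L)
  expect_setequal(scan$param, paste0("k", 1:16))
  base <- unlist(coarse_config()$kinetics[paste0("k", 1:16)])
  expect_true(all(scan$value >= 0.9 * base & scan$value <= 1.1 * base))
  expect_true(all(rep$verdicts))
})

test_that("reports serialize to plain lists losslessly", {
  rep <- cached("exp_wt", run_wildtype(coarse_config()))
  lst <- abcpattern:::report_to_list(rep)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lst, tmp, precision = 15L)
  back <- yaml::read_yaml(tmp)
  expect_equal(back$name, lst$name)
  expect_equal(back$verdicts, lst$verdicts)
  expect_equal(unlist(back$comparisons), unlist(lst$comparisons),
               tolerance = 1e-12)
})
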