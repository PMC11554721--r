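test_that("ideal adaptation markers follow the wall-shear and hoop-stress arguments", {
  expect_equal(ideal_adaptation(1, 1), tibble::tibble(a_ratio = 1, h_ratio = 1))
  ia <- ideal_adaptation(1, 1.1)
  expect_equal(ia$a_ratio, 1.1^(1 / 3))
  expect_equal(round(ia$a_ratio, 2), 1.03)
  ia2 <- ideal_adaptation(1.15, 1)
  expect_equal(ia2$h_ratio, 1.15)
})

test_that("the homeostatic state is a fixed point of the staggered stepper", {
  run <- run_scenario("sensitivity_sweep", overrides = list(gamma = 1),
                      t_end_norm = 2)
  ts <- run$timeseries
  expect_equal(ts$r_inner_norm, rep(1, nrow(ts)), tolerance = 1e-9)
  expect_equal(ts$h_norm, rep(1, nrow(ts)), tolerance = 1e-9)
  expect_equal(ts$trace_norm, rep(1, nrow(ts)), tolerance = 1e-9)
  # first record is the baseline with all normalized quantities at 1
  expect_equal(unlist(ts[1, c("r_inner_norm", "h_norm", "trace_norm",
                              "smc_stress_norm", "wss_ratio")]),
               c(r_inner_norm = 1, h_norm = 1, trace_norm = 1,
                 smc_stress_norm = 1, wss_ratio = 1), tolerance = 1e-9)
})

test_that("identical configurations produce bit-identical trajectories", {
  a <- run_scenario("sensitivity_sweep",
                    overrides = list(gamma = 1.1, s_sigma = 0.75),
                    t_end_norm = 1)
  b <- run_scenario("sensitivity_sweep",
                    overrides = list(gamma = 1.1, s_sigma = 0.75),
                    t_end_norm = 1)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$manifest$config_hash, b$manifest$config_hash)
})

test_that("the documented sub-step ordering is load-bearing", {
  cfg <- simulation_config(
    mode = "signaling", intramural = fixture_network("three_node"),
    gamma = 1.1, s_sigma = 0.75, t_end_norm = 1,
    outputs = list(collagen = "collagen", proliferation = "proliferation"),
    scenario = "order-test")
  default_run <- run_gr(cfg)
  permuted <- run_gr(cfg, order = c("signaling", "mechanics",
                                    "biochemistry"))
  expect_false(isTRUE(all.equal(default_run$timeseries$h_norm,
                                permuted$timeseries$h_norm)))
  sim <- init_simulation(cfg)
  expect_error(staggered_step(sim, order = c("mechanics", "mechanics",
                                             "signaling")),
               "permutation")
})

test_that("the uncoupled phenomenological pathway adapts to a pressure step", {
  run <- run_scenario("uncoupled",
                      overrides = list(gamma = 1.15, k_rate = 0.05),
                      t_end_norm = 6)
  ts <- run$timeseries
  expect_gt(dplyr::last(ts$h_norm), 1.03)
  # stress deviation decays from its initial jump
  dev <- abs(ts$smc_stress_norm - 1)
  expect_lt(dplyr::last(dev), max(dev) / 2)
})

test_that("pressure and flow steps move geometry in the physiological direction", {
  press <- run_scenario("angii_hypertension",
                        overrides = list(gamma = 1.15), t_end_norm = 3)
  expect_gt(dplyr::last(press$timeseries$h_norm), 1.01)
  flow <- run_scenario("ec_communication",
                       overrides = list(epsilon = 1.1), t_end_norm = 3)
  ts <- flow$timeseries
  expect_gt(dplyr::last(ts$r_inner_norm), 1.003)
  # wall shear stress relaxes back toward baseline as the lumen widens
  expect_lt(dplyr::last(ts$wss_ratio), max(ts$wss_ratio))
})

test_that("scenario presets are enumerable and unknown presets rejected", {
  sc <- list_scenarios()
  expect_setequal(sc$scenario, c("angii_hypertension", "ec_communication",
                                 "sensitivity_sweep", "uncoupled"))
  expect_error(run_scenario("no_such_preset"))
  expect_error(simulation_config(mode = "signaling"), "intramural")
  expect_error(simulation_config(mode = "phenomenological",
                                 diffusion = TRUE), "endothelial")
})

test_that("tidiers and plots expose the run in standard shapes", {
  run <- run_scenario("sensitivity_sweep",
                      overrides = list(gamma = 1.05), t_end_norm = 1)
  long <- generics::tidy(run)
  expect_true(all(c("step", "s", "s_norm", "quantity", "value") %in%
                    names(long)))
  expect_gt(nrow(long), nrow(run$timeseries))
  g <- generics::glance(run)
  expect_equal(nrow(g), 1)
  expect_equal(g$h_ideal, 1.05)
  p <- ggplot2::autoplot(run)
  expect_s3_class(p, "ggplot")
  p2 <- plot_species_profile(
    diffusible_steady_solve(3300, 15, 1.06e-14, 0.9, 647, 40), "NO")
  expect_s3_class(p2, "ggplot")
})
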