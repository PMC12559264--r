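test_that("identical configurations give bit-identical results", {
  cfg <- scenario_config(vvc_enabled = TRUE, pvr_ratio = 1.2)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$oxygen$sao2, b$oxygen$sao2)
  expect_identical(a$hemodynamics$edge_flows, b$hemodynamics$edge_flows)
  expect_identical(a$indices$sw, b$indices$sw)
  expect_identical(a$config_hash, b$config_hash)
  # different configuration, different hash
  expect_false(identical(a$config_hash, baseline_result()$config_hash))
})

test_that("a 1x1 sweep equals the standalone scenario run", {
  sw <- run_sweep(pvr_ratios = 1, doses = 0, collaterals = "vvc_apc")
  expect_equal(nrow(sw), 1)
  res <- vvc_apc_result()
  expect_equal(sw$sao2, res$oxygen$sao2, tolerance = 1e-9)
  expect_equal(sw$co, res$hemodynamics$co, tolerance = 1e-9)
  expect_equal(sw$ees_over_ea, res$indices$ees_over_ea, tolerance = 1e-9)
  expect_error(run_sweep(pvr_ratios = numeric(0)), "empty grid")
  expect_error(run_sweep(collaterals = "everything"), "unknown collateral")
})

test_that("failed sweep cells are recorded and the rest computed", {
  # vo2i far above the supportable maximum makes the oxygen solve fail
  pat <- patient_parameters(vo2i_rest = 600)
  sw <- suppressWarnings(
    run_sweep(pvr_ratios = 1, doses = c(0), collaterals = c("none"),
              patient = pat))
  expect_equal(nrow(sw), 1)
  expect_true(is.na(sw$sao2))
  expect_match(sw$error, "vo2i")
})

test_that("calibration is a no-op when targets are already met", {
  res <- vvc_apc_result()
  targets <- list(list(quantity = "sao2", value = res$oxygen$sao2,
                       config = res$config))
  out <- calibrate_registry(targets,
                            free = list("shunts.vvc.conductance" = c(0.05, 1)))
  expect_true(out$success)
  expect_equal(out$registry, default_registry())
  expect_lt(abs(out$residuals), 1e-9)
})

test_that("single-parameter bisection recovers a saturation target", {
  # the model's SaO2 is monotone in the VVC conductance, so bisection
  # from a detuned registry must recover the shipped operating point
  reg <- set_registry_value(default_registry(),
                            "shunts.vvc.conductance", 0.4)
  target <- vvc_apc_result()$oxygen$sao2
  cfg <- scenario_config(vvc_enabled = TRUE, apc_enabled = TRUE)
  out <- calibrate_registry(
    list(list(quantity = "sao2", value = target, config = cfg)),
    free = list("shunts.vvc.conductance" = c(0.02, 0.8)),
    registry = reg, residual_tol = 0.1)
  expect_true(out$success)
  expect_lt(abs(out$residuals), 0.1)
  expect_equal(unname(out$values), 0.19, tolerance = 0.1)
})

test_that("an unreachable target produces a calibration-failure report", {
  # with a VVC present, SaO2 cannot exceed the end-capillary saturation
  cfg <- scenario_config(vvc_enabled = TRUE)
  expect_warning(
    out <- calibrate_registry(
      list(list(quantity = "sao2", value = 99.9, config = cfg)),
      free = list("shunts.vvc.conductance" = c(0.05, 0.5))),
    "calibration failure")
  expect_false(out$success)
  expect_error(
    calibrate_registry(
      list(list(quantity = "sao2", value = 95, config = cfg)),
      free = list("shunts.vvc.conductance" = c(0.05, 0.5),
                  "shunts.apc.conductance" = c(0.05, 0.5))),
    "more free parameters")
})

test_that("registry paths read and write every supported component", {
  reg <- default_registry()
  for (path in c("shunts.vvc.conductance", "oxygen.s_pulm_cap",
                 "chambers.ventricle.e_max", "edges.rlung.R",
                 "dobutamine.svr.10")) {
    v <- get_registry_value(reg, path)
    reg2 <- set_registry_value(reg, path, v * 1.1)
    expect_equal(get_registry_value(reg2, path), v * 1.1)
  }
  expect_error(get_registry_value(reg, "nonsense.path"), "registry path")
})

test_that("generated fixtures agree with the package computations", {
  dir <- tempfile()
  generate_fixtures("rc_loop", dir)
  generate_fixtures("two_node_mixing", dir)
  generate_fixtures("rectangle_pv", dir)
  generate_fixtures("reference_scenarios", dir)

  rc <- yaml::read_yaml(file.path(dir, "rc_loop.yaml"))
  expect_equal(rc$tau, rc$R * rc$C1 * rc$C2 / (rc$C1 + rc$C2))

  mx <- read.csv(file.path(dir, "two_node_mixing_expected.csv"))
  spec <- yaml::read_yaml(file.path(dir, "two_node_mixing.yaml"))
  inst <- two_node_mixing_instance(spec$shunt_fraction, spec$q_total)
  ox <- solve_saturations(inst$mean, inst$topology,
                          fick_parameters(hb = spec$hb, vo2i = spec$vo2i,
                                          s_pulm_cap = spec$s_pulm_cap),
                          patient_parameters(bsa = spec$bsa))
  expect_equal(ox$sao2, mx$sao2, tolerance = 1e-9)

  pv <- read.csv(file.path(dir, "rectangle_pv.csv"))
  exp_pv <- read.csv(file.path(dir, "rectangle_pv_expected.csv"))
  expect_equal(max(pv$volume), exp_pv$edv)
  expect_equal(100 * (exp_pv$edv - exp_pv$esv) / exp_pv$edv, exp_pv$ef)

  scen <- yaml::read_yaml(file.path(dir, "reference_scenarios.yaml"))
  expect_equal(length(scen), 4)
})
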