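test_that("oxygen content and Fick formulas match hand arithmetic", {
  expect_equal(o2_content(97, 15, 100), 20.098, tolerance = 1e-12)
  expect_equal(o2_content(60, 15, 40), 12.364, tolerance = 1e-12)
  expect_equal(o2_content(0, 12, 0), 0)
  expect_error(o2_content(101, 15, 100), "saturation")
  expect_error(o2_content(-1, 15, 100), "saturation")

  expect_equal(fick_vo2(3.0, 20.098, 12.364), 232.02, tolerance = 1e-12)
  expect_equal(fick_vo2(2.5, 18, 18), 0)
  expect_equal(fick_vo2(0, 20, 12), 0)
  expect_error(fick_vo2(-1, 20, 12), "coi")

  # content/saturation conversion round-trips
  s <- c(12, 54, 97.3)
  expect_equal(o2_saturation_from_content(o2_content(s, 15, 40), 15, 40), s)
})

test_that("two-node shunt mixing matches the closed-form algebra", {
  f <- 0.1; spc <- 98; hb <- 15; vo2i <- 125; bsa <- 1.63; q <- 50
  inst <- two_node_mixing_instance(shunt_fraction = f, q_total = q)
  fick <- fick_parameters(hb = hb, vo2i = vo2i, s_pulm_cap = spc)
  pat <- patient_parameters(bsa = bsa, hb = hb)

  # independent algebra: Sv = Sa - drop, Sa = (1-f) spc + f Sv
  k <- 100 / (hb * 1.36)
  drop_s <- (vo2i * bsa / (10 * q * 0.06) - (100 - 40) * 0.0031) * k
  sv <- ((1 - f) * spc - drop_s) / (1 - f)
  sa <- (1 - f) * spc + f * sv

  ox <- solve_saturations(inst$mean, inst$topology, fick, pat)
  expect_equal(ox$sao2, sa, tolerance = 1e-6)
  expect_equal(unname(ox$saturations["ven"]), sv, tolerance = 1e-6)

  lin <- solve_saturations(inst$mean, inst$topology, fick, pat,
                           method = "linear")
  expect_equal(ox$saturations, lin$saturations, tolerance = 1e-9)
})

test_that("fixed point matches the direct linear solve on the full network", {
  res <- vvc_apc_result()
  topo <- build_fontan_topology(scenario_config(vvc_enabled = TRUE,
                                                apc_enabled = TRUE))
  fick <- fick_parameters(s_pulm_cap = default_registry()$oxygen$s_pulm_cap)
  fp <- solve_saturations(res$hemodynamics, topo, fick)
  lin <- solve_saturations(res$hemodynamics, topo, fick, method = "linear")
  expect_equal(fp$saturations, lin$saturations, tolerance = 1e-9)
})

test_that("Fick closure holds at every solved operating point", {
  for (res in list(baseline_result(), vvc_apc_result(),
                   dobutamine_result())) {
    ox <- res$oxygen
    expect_lt(ox$fick_residual, 1e-6 * ox$fick$vo2i)
    expect_gte(ox$cao2, ox$cvo2)
    expect_true(all(ox$saturations >= 0 & ox$saturations <= 100))
  }
})

test_that("saturations respond monotonically to shunting and consumption", {
  res <- vvc_apc_result()
  topo <- build_fontan_topology(scenario_config(vvc_enabled = TRUE,
                                                apc_enabled = TRUE))
  reg <- default_registry()
  base_fick <- fick_parameters(s_pulm_cap = reg$oxygen$s_pulm_cap)

  # at fixed flows, a larger VVC flow share strictly lowers SaO2
  mean_hi <- res$hemodynamics
  mean_hi$edge_flows["vvc"] <- mean_hi$edge_flows["vvc"] * 2
  mean_hi$edge_flows["rlung"] <- mean_hi$edge_flows["rlung"] -
    mean_hi$edge_flows["vvc"] / 2
  sa0 <- solve_saturations(res$hemodynamics, topo, base_fick)$sao2
  sa1 <- solve_saturations(mean_hi, topo, base_fick)$sao2
  expect_lt(sa1, sa0)

  # increasing vo2i strictly lowers SvO2
  sv <- vapply(c(100, 125, 150), function(v)
    solve_saturations(res$hemodynamics, topo,
                      fick_parameters(vo2i = v,
                                      s_pulm_cap = reg$oxygen$s_pulm_cap))$svo2,
    numeric(1))
  expect_true(all(diff(sv) < 0))
})

test_that("infeasible oxygen consumption is reported with the supportable maximum", {
  res <- baseline_result()
  topo <- build_fontan_topology(scenario_config())
  err <- tryCatch(
    solve_saturations(res$hemodynamics, topo,
                      fick_parameters(vo2i = 600)),
    error = function(e) conditionMessage(e))
  expect_match(err, "maximum supportable vo2i")
})
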