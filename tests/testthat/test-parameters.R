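test_that("defaults resolve to the reference patient and resistances", {
  cfg <- load_config("", quiet = TRUE)
  expect_equal(cfg$patient$bsa, 1.63)
  expect_equal(cfg$patient$hb, 15)
  expect_equal(cfg$scenario$svr_baseline, 0.9)
  expect_equal(cfg$scenario$pvr_baseline, 0.05)
  expect_equal(cfg$scenario$initial_sao2, 97)
  expect_equal(cfg$scenario$initial_svo2, 60)

  reg <- default_registry()
  expect_equal(reg$reference$svr, 0.9)
  expect_equal(reg$reference$pvr, 0.05)
  expect_equal(systemic_resistance(reg), 0.9)
  expect_equal(pulmonary_resistance(reg), 0.05)
})

test_that("registry is complete and physically positive", {
  reg <- default_registry()
  topo <- build_fontan_topology(
    scenario_config(vvc_enabled = TRUE, apc_enabled = TRUE), reg)
  referenced <- unique(c(topo$edges$from, topo$edges$to))
  expect_true(all(referenced %in% topo$compartments$name))
  expect_true(all(reg$compartments$C > 0))
  expect_true(all(reg$edges$R >= 0))
  expect_true(all(reg$edges$L >= 0))
  for (sh in reg$shunts) expect_gte(sh$conductance, 0)
  # dose-response sanity: identity at dose 0, monotone columns
  expect_equal(unlist(reg$dobutamine[reg$dobutamine$dose == 0, -1]),
               c(e_max = 1, svr = 1, heart_rate = 1, vo2i = 1))
  expect_true(all(diff(reg$dobutamine$e_max) >= 0))
  expect_true(all(diff(reg$dobutamine$svr) <= 0))
})

test_that("configuration validation names the offending key", {
  expect_error(scenario_config(pvr_ratio = 2.5), "pvr_ratio")
  expect_error(scenario_config(dobutamine_dose = -1), "dobutamine_dose")
  expect_error(scenario_config(initial_sao2 = 0), "initial_sao2")
  expect_error(scenario_config(svr_baseline = 0.04, pvr_baseline = 0.05),
               "svr_baseline")
  expect_error(patient_parameters(heart_rate = 300), "heart_rate")
  expect_error(load_config("scenario: {bogus_key: 1}", quiet = TRUE),
               "bogus_key")
  expect_error(load_config("compartments: {neck: {C: 1}}", quiet = TRUE),
               "neck")
  # out-of-range ratio accepted with the explicit override
  expect_equal(
    scenario_config(pvr_ratio = 2.5, allow_extended_ratios = TRUE)$pvr_ratio,
    2.5)
})

test_that("serialize/load round-trips a resolved configuration", {
  cfg <- load_config(
    "scenario: {pvr_ratio: 1.4, vvc_enabled: yes, dobutamine_dose: 5}\npatient: {heart_rate: 95}",
    quiet = TRUE)
  back <- load_config(serialize_config(cfg), quiet = TRUE)
  expect_identical(unclass(back$patient), unclass(cfg$patient))
  expect_identical(unclass(back$scenario), unclass(cfg$scenario))
})

test_that("registry overrides apply to named components only", {
  cfg <- load_config(
    "shunts: {vvc: {conductance: 0.5}}\noxygen: {s_pulm_cap: 97.5}\nchambers: {ventricle: {e_max: 3.5}}",
    quiet = TRUE)
  expect_equal(cfg$registry$shunts$vvc$conductance, 0.5)
  expect_equal(cfg$registry$oxygen$s_pulm_cap, 97.5)
  expect_equal(cfg$registry$chambers$ventricle$e_max, 3.5)
  # untouched parts equal the defaults
  expect_equal(cfg$registry$edges, default_registry()$edges)
})
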