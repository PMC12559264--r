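test_that("built Fontan topology honors the shunt flags and the TCPC", {
  no_shunts <- build_fontan_topology(
    scenario_config(fenestration_enabled = FALSE))
  expect_equal(sum(no_shunts$edges$type == "shunt"), 0)
  expect_equal(nrow(validate_topology(no_shunts)), 0)

  all_shunts <- build_fontan_topology(
    scenario_config(vvc_enabled = TRUE, apc_enabled = TRUE))
  sh <- all_shunts$edges[all_shunts$edges$type == "shunt", ]
  expect_equal(nrow(sh), 3)
  expect_setequal(sh$name, c("fenestration", "vvc", "apc"))
  cls <- all_shunts$node_class
  expect_equal(unname(cls[sh$from[sh$name == "vvc"]]), "systemic_venous")
  expect_equal(unname(cls[sh$to[sh$name == "vvc"]]), "pulmonary_venous")
  expect_equal(unname(cls[sh$from[sh$name == "apc"]]), "systemic_arterial")
  expect_equal(unname(cls[sh$to[sh$name == "apc"]]), "pulmonary_arterial")
  expect_equal(sh$from[sh$name == "fenestration"], "conduit")
  expect_equal(sh$to[sh$name == "fenestration"], "atrium")
  expect_equal(nrow(validate_topology(all_shunts)), 0)

  # a registry gap is reported by name
  reg <- default_registry()
  reg$compartments <- reg$compartments[reg$compartments$name != "svc", ]
  expect_error(build_fontan_topology(scenario_config(), reg), "svc")
})

test_that("attach_shunt enforces kind-consistent endpoints", {
  topo <- build_fontan_topology(scenario_config(fenestration_enabled = FALSE))
  ok <- attach_shunt(topo, shunt_parameters("VVC", "conduit", "pv", 0.2))
  expect_equal(sum(ok$edges$type == "shunt"), 1)
  # original topology unchanged
  expect_equal(sum(topo$edges$type == "shunt"), 0)
  expect_error(
    attach_shunt(topo, shunt_parameters("VVC", "aorta", "pv", 0.2)),
    "kind-inconsistent")
  expect_error(
    attach_shunt(topo, shunt_parameters("APC", "aorta", "pv", 0.2)),
    "kind-inconsistent")
  expect_error(
    attach_shunt(topo, shunt_parameters("fenestration", "svc", "atrium", 0.2)),
    "kind-inconsistent")
  expect_error(
    attach_shunt(topo, shunt_parameters("VVC", "nowhere", "pv", 0.2)),
    "nowhere")
  # zero-conductance shunt is accepted and carries no flow
  z <- attach_shunt(topo, shunt_parameters("VVC", "conduit", "pv", 0))
  expect_equal(shunt_flow(5, z$shunts$vvc), 0)
})

test_that("shunt attachment is order-independent", {
  topo <- build_fontan_topology(scenario_config(fenestration_enabled = FALSE))
  vvc <- shunt_parameters("VVC", "conduit", "pv", 0.2, exponent = 3)
  apc <- shunt_parameters("APC", "aorta", "lpa", 0.3)
  a <- attach_shunt(attach_shunt(topo, vvc), apc)
  b <- attach_shunt(attach_shunt(topo, apc), vvc)
  ea <- a$edges[order(a$edges$name), ]
  eb <- b$edges[order(b$edges$name), ]
  rownames(ea) <- rownames(eb) <- NULL
  expect_identical(ea, eb)
})

test_that("validate_topology reports TCPC breaches and bad parameters", {
  topo <- build_fontan_topology(scenario_config())
  bad <- topo
  bad$edges <- rbind(bad$edges, data.frame(
    name = "svc_atrium", from = "svc", to = "atrium", type = "resistor",
    R = 0.1, L = 0, class = "other", bed = FALSE, g = 0, n = 1,
    w = NA_real_))
  rep <- validate_topology(bad)
  expect_true(any(rep$check == "tcpc"))

  bad2 <- topo
  bad2$compartments$C[bad2$compartments$name == "aorta"] <- -1
  rep2 <- validate_topology(bad2)
  expect_true(any(rep2$check == "parameters"))

  bad3 <- topo
  bad3$edges <- bad3$edges[bad3$edges$name != "pulm_ven", ]
  rep3 <- validate_topology(bad3)
  expect_true(any(rep3$check == "connectivity"))
})

test_that("topology serializes to parseable YAML", {
  topo <- build_fontan_topology(scenario_config())
  doc <- yaml::yaml.load(serialize_topology(topo))
  expect_setequal(names(doc), c("compartments", "chambers", "edges"))
  expect_equal(length(doc$compartments$name), nrow(topo$compartments))
})
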