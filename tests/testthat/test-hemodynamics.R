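test_that("equilibrium states have zero derivative", {
  topo <- rc_loop_topology(R = 1, C1 = 2, C2 = 3)
  # both compartments at 5 mmHg
  d <- state_derivative(topo, c(a = 10, b = 15), 0, 1)
  expect_equal(unname(d$dstate), c(0, 0))
  expect_equal(unname(d$flows), 0)
})

test_that("volume is conserved by construction for arbitrary states", {
  topo <- build_fontan_topology(scenario_config(vvc_enabled = TRUE,
                                                apc_enabled = TRUE))
  st0 <- initial_state(topo)
  set.seed(42)
  for (i in 1:20) {
    st <- st0 * stats::runif(length(st0), 0.5, 1.5)
    d <- state_derivative(topo, st, stats::runif(1, 0, 0.75), 0.75)
    expect_lt(abs(sum(d$dstate[seq_len(11)])), 1e-9)
  }
  bad <- st0; bad[3] <- NaN
  expect_error(state_derivative(topo, bad, 0, 0.75), "non-finite")
})

test_that("RC loop transient matches the closed-form decay", {
  R <- 1; C1 <- 2; C2 <- 3
  topo <- rc_loop_topology(R = R, C1 = C1, C2 = C2)
  tau <- R * C1 * C2 / (C1 + C2)
  y0 <- unname(initial_state(topo))   # 10 mmHg vs 0 mmHg
  f <- function(t, y, p) list(state_derivative(topo, y, t, 1)$dstate)
  out <- deSolve::ode(y0, seq(0, 3, by = 0.05), f, NULL,
                      rtol = 1e-9, atol = 1e-12)
  dp <- out[, 2] / C1 - out[, 3] / C2
  expected <- 10 * exp(-out[, 1] / tau)
  expect_lt(max(abs(dp - expected)) / 10, 0.005)
})

test_that("R and compiled right-hand sides agree to rounding error", {
  topo <- build_fontan_topology(scenario_config(vvc_enabled = TRUE,
                                                apc_enabled = TRUE))
  p <- fontansim:::compile_topology(topo, 0.75)
  st0 <- unname(initial_state(topo))
  set.seed(7)
  for (i in 1:10) {
    st <- st0 * stats::runif(length(st0), 0.6, 1.4)
    tt <- stats::runif(1, 0, 0.75)
    a <- fontansim:::rhs_r(tt, st, p)
    b <- fontansim:::fontan_rhs(tt, st, p)
    expect_equal(a[[1]], b[[1]], tolerance = 1e-12)
    expect_equal(a[[2]], b[[2]], tolerance = 1e-12)
  }
})

test_that("limit cycle converges, conserves volume, and is a fixed point", {
  sol <- toy_solution()
  expect_lt(sol$total_volume_drift, 1e-3)
  expect_lt(utils::tail(sol$residuals, 1), 1e-4)
  # first and last samples agree within the convergence tolerance
  ns <- ncol(sol$states)
  rel <- max(abs(sol$states[1, ] - sol$states[nrow(sol$states), ]) /
               pmax(abs(sol$states[1, ]), 1))
  expect_lt(rel, 1e-3)
  # restarting from the converged state converges almost immediately
  sol2 <- run_to_limit_cycle(toy_loop_topology(), patient_parameters(),
                             init = sol$final_state)
  expect_lte(sol2$beats, 2)
})

test_that("a non-pumping chamber pair settles to zero flow", {
  topo <- toy_loop_topology(e_max = 0.1, e_min = 0.1)
  topo$chambers$atrium <- chamber_parameters(
    e_max = 0.16, e_min = 0.16, v0 = 4, activation_onset = 0.8,
    tau1_frac = 0.11, tau2_frac = 0.18, m1 = 1.9, m2 = 13)
  sol <- run_to_limit_cycle(topo, patient_parameters())
  mh <- beat_averages(sol)
  expect_lt(abs(mh$co), 1e-3)
  expect_lt(abs(mh$net_co), 1e-3)
  expect_lt(max(abs(sol$flows)), 0.1)
})

test_that("beat averages satisfy junction balance and flow accounting", {
  res <- no_shunt_result()
  mh <- res$hemodynamics
  expect_lt(mh$balance, 1e-3)
  # no recirculation path: aortic output equals caval return
  expect_equal(mh$co, mh$net_co, tolerance = 1e-3)

  res2 <- vvc_apc_result()
  mh2 <- res2$hemodynamics
  expect_lt(mh2$balance, 1e-3)
  expect_gt(mh2$co, mh2$net_co)
  # mass balance: CO - net CO = APC + fenestration + VVC flow
  q <- mh2$edge_flows
  expect_equal(mh2$co - mh2$net_co,
               unname(q["apc"] + q["fenestration"] + q["vvc"]) * 0.06,
               tolerance = 1e-3)
})

test_that("a passive three-compartment ring relaxes to the analytic equilibrium", {
  comp <- data.frame(name = c("a", "b", "c"), C = c(1, 2, 4),
                     V0 = c(5, 5, 5), init_pressure = c(20, 5, 1),
                     kind = "vascular")
  edges <- data.frame(name = c("ab", "bc", "ca"),
                      from = c("a", "b", "c"), to = c("b", "c", "a"),
                      type = "resistor", R = c(0.5, 1, 2), L = 0,
                      class = "other", bed = FALSE, g = 0, n = 1,
                      w = NA_real_)
  topo <- structure(list(compartments = comp, chambers = list(),
                         edges = edges,
                         node_class = c(a = "other", b = "other", c = "other"),
                         shunts = list()),
                    class = "fontan_topology")
  sol <- run_to_limit_cycle(topo, patient_parameters(),
                            control = limit_cycle_control(cycle_tol = 1e-6))
  p_inf <- sum(c(1, 2, 4) * c(20, 5, 1)) / sum(c(1, 2, 4))
  mh <- beat_averages(sol)
  expect_equal(unname(mh$node_pressures), rep(p_inf, 3), tolerance = 1e-3)
  expect_lt(max(abs(mh$edge_flows)) / p_inf, 0.005)
})

test_that("beat CSV export writes one row per sample", {
  sol <- toy_solution()
  path <- tempfile(fileext = ".csv")
  export_beat_csv(sol, path)
  df <- read.csv(path)
  expect_equal(nrow(df), length(sol$time))
  expect_true(all(c("time", "P_ventricle", "Q_aortic") %in% names(df)))
})
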