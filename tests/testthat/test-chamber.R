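test_that("elastance waveform is periodic, bounded and attains its peak", {
  ch <- chamber_parameters(e_max = 2.9, e_min = 0.11, v0 = 8)
  period <- 0.75
  t <- seq(0, period, length.out = 2001)
  e <- elastance_at(ch, t, period)
  expect_true(all(e >= ch$e_min - 1e-12))
  expect_true(all(e <= ch$e_max + 1e-12))
  expect_equal(elastance_at(ch, 0, period), ch$e_min, tolerance = 1e-6)
  expect_equal(max(e), ch$e_max, tolerance = 1e-4)
  # periodicity
  expect_equal(elastance_at(ch, t, period),
               elastance_at(ch, t + period, period))
  expect_gt(mean(e), 0)
  # degenerate chamber: constant elastance
  flat <- chamber_parameters(e_max = 1, e_min = 1, v0 = 0)
  expect_equal(elastance_at(flat, t, period), rep(1, length(t)))
})

test_that("chamber pressure follows the elastance law plus viscous term", {
  ch <- chamber_parameters(e_max = 2, e_min = 2, v0 = 10)
  expect_equal(chamber_pressure(ch, 110, 0, 0, 0.75), 200)
  expect_equal(chamber_pressure(ch, 10, 0, 0.3, 0.75), 0)
  chv <- chamber_parameters(e_max = 2, e_min = 2, v0 = 10,
                            viscoelastic_coefficient = 0.05)
  expect_equal(chamber_pressure(chv, 110, -100, 0, 0.75), 200 - 5)
  # monotone in volume at fixed time
  ch2 <- chamber_parameters(e_max = 2.9, e_min = 0.11, v0 = 8)
  p <- chamber_pressure(ch2, c(20, 40, 80), 0, 0.2, 0.75)
  expect_true(all(diff(p) > 0))
  expect_error(chamber_pressure(ch2, -5, 0, 0, 0.75), "volume")
  expect_error(chamber_parameters(e_max = 1, e_min = 2, v0 = 0), "e_max")
})

test_that("regularized-diode valve is continuous, monotone, Ohmic forward", {
  v <- valve_parameters(forward_resistance = 0.1)
  expect_equal(valve_flow(0, v), 0)
  expect_equal(valve_flow(10, v), 100, tolerance = 0.01)
  expect_equal(valve_flow(-10, v), 0)
  dp <- seq(-5, 5, by = 0.01)
  q <- valve_flow(dp, v)
  expect_true(all(diff(q) >= 0))
  expect_true(all(diff(valve_flow(seq(0.01, 5, by = 0.01), v)) > 0))
  # continuity across the blend boundaries
  w <- v$smoothing_width
  expect_equal(valve_flow(2 * w - 1e-9, v), valve_flow(2 * w + 1e-9, v),
               tolerance = 1e-6)
  # reverse leak
  leaky <- valve_parameters(forward_resistance = 0.1, leak_conductance = 0.02)
  expect_equal(valve_flow(-10, leaky), -0.2, tolerance = 1e-6)
})

test_that("raising e_max raises peak ventricular pressure at fixed afterload", {
  ctrl <- limit_cycle_control(sample_dt = 2e-3)
  peak <- function(emx) {
    sol <- run_to_limit_cycle(toy_loop_topology(e_max = emx),
                              patient_parameters(), control = ctrl)
    max(sol$pressures[, "ventricle"])
  }
  p <- vapply(c(1.5, 2.5, 3.5), peak, numeric(1))
  expect_true(all(diff(p) > 0))
})
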