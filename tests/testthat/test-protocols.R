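test_that("the PI law reproduces hand-computed updates with anti-windup", {
  ctrl <- pi_controller()
  # first sample at 37 degC: e = 18, integral = 0.36 degC s
  c1 <- pi_update(ctrl, 37)
  expect_equal(c1$V, 4.6 * 18 + 5.8 * 18 * 0.02)
  expect_equal(c1$V, 84.888)
  # zero error: pure integral hold
  c1$integral <- 2
  c2 <- pi_update(c1, 55)
  expect_equal(c2$V, 5.8 * 2)
  # large overshoot: output clamps at zero and the integral freezes
  c3 <- pi_controller(); c3$integral <- -100
  c4 <- pi_update(c3, 75)
  expect_equal(c4$V, 0)
  expect_equal(c4$integral, -100)
})

test_that("the sensor reads the maximum nodal temperature in its box", {
  cfg <- scenario_config("RFA", "monopolar", mesh_resolution = "coarse",
                         half_domain = TRUE)
  m <- generate_mesh(build_geometry(cfg))
  st <- thermal_state(m)
  expect_equal(sensor_temperature(st), 37)
  # monotone field: the sensor returns its hottest node
  st$T <- 37 + 100 * (m$nodes[, 3] - min(m$nodes[, 3]))
  expect_equal(sensor_temperature(st), max(st$T[m$sensor_nodes]))
  expect_error(sensor_temperature(st, integer(0)), "empty sensor")
})

test_that("a disabled controller delivers no energy", {
  cfg <- scenario_config("RFA", "monopolar", inlet_velocity = 0,
                         duration = 0.1, mesh_resolution = "paper",
                         half_domain = TRUE)
  run <- run_rfa(cfg, controller = pi_controller(K_P = 0, K_I = 0))
  expect_equal(max(abs(run$trace$V)), 0)
  expect_equal(run$state$T, rep(37, length(run$state$T)), tolerance = 1e-9)
})

test_that("identical configurations give bit-identical traces", {
  cfg <- scenario_config("RFA", "monopolar", inlet_velocity = 0.06,
                         duration = 0.2, mesh_resolution = "paper",
                         half_domain = TRUE)
  mesh <- generate_mesh(build_geometry(cfg))
  flow <- suppressWarnings(solve_stationary_flow(mesh, cfg$inlet_velocity))
  flow2 <- suppressWarnings(solve_stationary_flow(mesh, cfg$inlet_velocity))
  expect_identical(flow$u, flow2$u)
  r1 <- run_rfa(cfg, mesh = mesh, flow = flow)
  r2 <- run_rfa(cfg, mesh = mesh, flow = flow)
  expect_identical(r1$trace, r2$trace)
})

test_that("the RFA reference settles at the 55 degC setpoint", {
  run <- rfa_mono_reference()
  tr <- run$trace
  # target reached in under 5 s
  expect_lt(tr$t[which(tr$T_sensor >= 55)[1]], 5)
  # steady-state error within 1 degC over the last 20 s, no 5 degC overshoot
  late <- tr$T_sensor[tr$t > 10]
  expect_true(all(abs(late - 55) <= 1))
  expect_lte(max(tr$T_sensor), 60)
  expect_equal(tr$t[nrow(tr)], 30, tolerance = 1e-9)
})

test_that("PFA bursts spike during the pulse, relax between bursts, and keep the 1 Hz schedule", {
  cfg <- scenario_config("PFA", "monopolar", mesh_resolution = "paper",
                         half_domain = TRUE)
  run <- run_pfa(cfg, n_bursts = 3)
  tr <- run$trace
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$peak_blood >= tr$end_blood - 1e-9))
  expect_true(all(tr$rest_cardiac <= tr$end_cardiac + 1e-9))  # decay after pulse
  expect_equal(tr$t[3], 3, tolerance = 1e-9)                  # treatment clock
  expect_equal(diff(tr$t), c(1, 1), tolerance = 1e-9)         # 1 Hz repetition
  # a null amplitude produces no heating and no lesion
  cfg0 <- scenario_config("PFA", "monopolar", applied_voltage = 0,
                          mesh_resolution = "paper", half_domain = TRUE)
  run0 <- run_pfa(cfg0, n_bursts = 2)
  expect_equal(run0$state$T, rep(37, length(run0$state$T)), tolerance = 1e-9)
  expect_equal(max(run0$E_max_elem), 0)
})
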