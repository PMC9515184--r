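test_that("the Joule source is sigma |E|^2 and scales quadratically", {
  fs <- list(sigma = c(0.281, 0.5), E_elem = c(1e4, 0))
  q <- joule_source(fs)
  expect_equal(q$q, c(0.281 * 1e8, 0))
  fs2 <- list(sigma = c(0.281, 0.5), E_elem = 2 * c(1e4, 0))
  expect_equal(joule_source(fs2)$q, 4 * q$q)
})

test_that("no source and uniform boundaries keep the equilibrium at 37 degC", {
  fx <- make_analytic_fixture("uniform_plates")
  st <- thermal_state(fx$mesh, dirichlet_nodes = fx$mesh$active_nodes,
                      dirichlet_values = rep(37, length(fx$mesh$active_nodes)))
  for (i in 1:5) st <- step_temperature(st, NULL, 0.1)
  expect_equal(st$T, rep(37, length(st$T)), tolerance = 1e-10)
  expect_equal(st$t, 0.5)
  expect_error(step_temperature(st, NULL, -1), "positive")
})

test_that("transient conduction into a slab follows the erfc profile", {
  fx <- make_analytic_fixture("slab_conduction_1d", level = 2)
  m <- fx$mesh; p <- fx$params
  st <- thermal_state(
    m, dirichlet_nodes = c(p$surface_nodes, p$far_nodes),
    dirichlet_values = c(rep(p$T_s, length(p$surface_nodes)),
                         rep(37, length(p$far_nodes))),
    constant_properties = TRUE)
  dt <- 0.05
  checks <- 0
  for (i in 1:200) {
    st <- step_temperature(st, NULL, dt)
    if (any(abs(st$t - c(2, 5, 10)) < 1e-9)) {
      for (d in c(1e-3, 2e-3, 3e-3)) {
        sel <- which(abs(m$nodes[, 2] - 0.5e-3) < 1e-9 &
                     abs(m$nodes[, 3] - 0.5e-3) < 1e-9)
        sel <- sel[which.min(abs(m$nodes[sel, 1] - d))]
        Ta <- fx$analytic$T(m$nodes[sel, 1], st$t)
        expect_lt(abs(st$T[sel] - Ta) / (p$T_s - 37), 0.02)
        checks <- checks + 1
      }
    }
  }
  expect_equal(checks, 9)
})

test_that("a uniformly heated insulated block warms at q / (rho c)", {
  m <- ablatr:::.fixture_mesh(seq(0, 4e-3, 1e-3), seq(0, 4e-3, 1e-3),
                              seq(0, 4e-3, 1e-3))
  st <- thermal_state(m, dirichlet_nodes = integer(0),
                      dirichlet_values = numeric(0))
  q <- 1e7
  src <- structure(list(q = rep(q, nrow(m$elems))), class = "heat_source")
  for (i in 1:10) st <- step_temperature(st, src, 0.1)
  expect_equal((mean(st$T) - 37) / 1, q / (1081 * 3686), tolerance = 0.005)
})

test_that("the latent-heat band slows heating by the enthalpy ratio and conserves energy", {
  m <- ablatr:::.fixture_mesh(seq(0, 4e-3, 1e-3), seq(0, 4e-3, 1e-3),
                              seq(0, 4e-3, 1e-3))
  st <- thermal_state(m, dirichlet_nodes = integer(0),
                      dirichlet_values = numeric(0))
  src <- structure(list(q = rep(3e8, nrow(m$elems))), class = "heat_source")
  Ts <- numeric(200)
  for (i in 1:200) { st <- step_temperature(st, src, 0.02); Ts[i] <- max(st$T) }
  slopes <- diff(Ts) / 0.02
  pre <- mean(slopes[Ts[-1] > 40 & Ts[-1] < 95])
  in_band <- mean(slopes[Ts[-1] > 99.02 & Ts[-1] < 99.98])
  ratio_expected <- 2.162e9 / (1081 * 3686)
  expect_equal(pre / in_band, ratio_expected, tolerance = 0.02)
  # global energy audit: injected power equals stored enthalpy (insulated)
  H <- ablatr:::.total_enthalpy(st$model, st$T)
  E_in <- 3e8 * sum(m$vol) * 0.02 * 200
  expect_lt(abs(H - E_in) / E_in, 1e-8)
})

test_that("temperatures stay within physical bounds during an advected run", {
  run <- rfa_mono_reference()
  expect_gte(min(run$state$T), 37 - 1e-6)
  expect_gte(min(run$T_max), 37 - 1e-6)
})
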