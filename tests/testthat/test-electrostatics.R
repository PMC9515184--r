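test_that("RMS-equivalent voltages follow the waveform kind", {
  expect_equal(rms_equivalent_voltage("sinusoid", 100), 100 / sqrt(2))
  expect_equal(rms_equivalent_voltage("biphasic", 3100), 3100)
  expect_equal(rms_equivalent_voltage("sinusoid", 0), 0)
  expect_equal(rms_equivalent_voltage("biphasic", 0), 0)
  expect_error(rms_equivalent_voltage("triangle", 10))
})

test_that("parallel plates give a uniform field and conserve current", {
  fx <- make_analytic_fixture("uniform_plates")
  fs <- solve_potential(fx$mesh, sigma = rep(0.5, nrow(fx$mesh$elems)),
                        V = fx$params$V0)
  expect_equal(fs$E_elem, rep(fx$params$V0 / fx$params$d, length(fs$E_elem)),
               tolerance = 1e-6)
  expect_lt(fs$current_balance, 1e-4)
  expect_equal(fs$phi, fx$analytic$phi(fx$mesh$nodes), tolerance = 1e-9)
})

test_that("hemispherical electrode potential matches the closed form", {
  errs <- sapply(c(1, 1.4, 2), function(lev) {
    fx <- make_analytic_fixture("hemisphere_electrode", level = lev)
    m <- fx$mesh
    fs <- solve_potential(m, sigma = rep(0.2, nrow(m$elems)), V = fx$params$V0,
                          dirichlet_values = c(fx$params$active_values,
                                               fx$params$outer_values))
    free <- setdiff(seq_len(m$n_nodes), m$active_nodes)
    ana <- fx$analytic$phi(m$nodes)
    sqrt(sum((fs$phi[free] - ana[free])^2) / sum(ana[free]^2))
  })
  expect_lt(errs[1], 0.02)
  # L2 error decreases monotonically under refinement
  expect_true(all(diff(errs) < 0))
})

test_that("two-layer slab in series behaves like series resistors", {
  fx <- make_analytic_fixture("uniform_plates", level = 2)
  m <- fx$mesh
  d <- fx$params$d
  s1 <- 0.2; s2 <- 0.8
  sigma <- ifelse(m$centroids[, 3] < d / 2, s1, s2)
  fs <- solve_potential(m, sigma = sigma, V = fx$params$V0)
  E1 <- mean(fs$E_elem[m$centroids[, 3] < d / 2])
  E2 <- mean(fs$E_elem[m$centroids[, 3] >= d / 2])
  # field inversely proportional to conductivity, current density continuous
  expect_equal(E1 / E2, s2 / s1, tolerance = 1e-6)
  expect_equal(s1 * E1, s2 * E2, tolerance = s1 * E1 * 1e-6)
  expect_lt(fs$current_balance, 1e-4)
})

test_that("the discrete potential obeys the maximum principle and scales linearly", {
  m <- pfa_mono_small_mesh()
  sig <- ablatr:::sigma_map(m, "PFA", 37)
  fs1 <- solve_potential(m, sigma = sig, V = 100)
  expect_gte(min(fs1$phi), 0 - 1e-8 * 100)
  expect_lte(max(fs1$phi), 100 + 1e-8 * 100)
  expect_lt(fs1$current_balance, 1e-4)
  fs2 <- solve_potential(m, sigma = sig, V = 200)
  expect_equal(fs2$phi, 2 * fs1$phi, tolerance = 1e-10)
  expect_equal(fs2$E_elem, 2 * fs1$E_elem, tolerance = 1e-10)
})

test_that("the nonlinear electroporation solve has the expected fixed points", {
  m <- pfa_mono_small_mesh()
  fs0 <- solve_nonlinear_pfa_field(m, 37, 0)
  expect_equal(max(abs(fs0$phi)), 0)
  expect_true(fs0$converged)

  # uniform field far below the conductivity-rise threshold: the sigmoid is
  # flat, so the very first update is already converged
  fx <- make_analytic_fixture("uniform_plates")
  mm <- fx$mesh
  mm$region <- rep("cardiac", nrow(mm$elems))
  mm$n_nodes <- nrow(mm$nodes)
  fs <- solve_nonlinear_pfa_field(mm, 37, 2)   # 2 V over 2 mm = 10 V/cm
  expect_true(fs$converged)
  expect_lte(fs$iterations, 3)
  lin <- solve_potential(mm, sigma = rep(sigma_pfa(10, 37, "cardiac"),
                                         nrow(mm$elems)), V = 2)
  expect_equal(fs$phi, lin$phi, tolerance = 1e-6)

  # the 1000 V/cm lesion grows monotonically with the applied voltage
  mt1 <- lesion_metrics(extract_lesion_region(
    m, lesion_field_vcm_t(m, solve_nonlinear_pfa_field(m, 37, 2400)$E_elem), 1000))
  mt2 <- lesion_metrics(extract_lesion_region(
    m, lesion_field_vcm_t(m, solve_nonlinear_pfa_field(m, 37, 3100)$E_elem), 1000))
  expect_gt(mt2$V_mm3, mt1$V_mm3)
  expect_gt(mt2$depth_mm, mt1$depth_mm)
})
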