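test_that("RFA conductivity follows the exponential law with desiccation collapse", {
  expect_equal(sigma_rfa(37, "cardiac"), 0.281)
  expect_equal(sigma_rfa(50, "cardiac"), 0.281 * exp(0.015 * 13), tolerance = 1e-12)
  s100 <- 0.281 * exp(0.015 * 63)
  expect_equal(sigma_rfa(110, "cardiac"), 1e-4 * s100, tolerance = 1e-9)
  # continuity at the 100 and 105 degC breakpoints
  eps <- 1e-8
  expect_equal(sigma_rfa(100 - eps, "cardiac"), sigma_rfa(100 + eps, "cardiac"),
               tolerance = 1e-6)
  expect_equal(sigma_rfa(105 - eps, "cardiac"), sigma_rfa(105 + eps, "cardiac"),
               tolerance = 1e-4)
  # blood and skeletal keep the exponential branch (no vapor phase listed)
  expect_equal(sigma_rfa(50, "blood"), 0.748 * exp(0.015 * 13))
  expect_equal(sigma_rfa(50, "skeletal"), 0.446 * exp(0.015 * 13))
  # catheter materials are temperature-independent
  expect_equal(sigma_rfa(c(37, 80), "electrode"), rep(4.6e6, 2))
  expect_error(sigma_rfa(37, "kryptonite"), "unknown material")
})

test_that("PFA conductivity is a Gompertz sigmoid in field times the thermal factor", {
  expect_equal(sigma_pfa(0, 37, "cardiac"), 0.228, tolerance = 1e-6)
  expect_equal(sigma_pfa(1e9, 37, "cardiac"), 0.328, tolerance = 1e-9)
  expect_equal(sigma_pfa(500, 37, "cardiac"), 0.228 + 0.1 * exp(-1),
               tolerance = 1e-12)
  # monotone nondecreasing in |E| and bounded by the asymptotes
  E <- seq(0, 3000, by = 10)
  s <- sigma_pfa(E, 37, "cardiac")
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0.228 - 1e-12 & s <= 0.328 + 1e-12))
  # temperature factor matches the RFA pattern
  expect_equal(sigma_pfa(0, 50, "cardiac") / sigma_pfa(0, 37, "cardiac"),
               exp(0.015 * 13), tolerance = 1e-9)
})

test_that("the printed thermal factor at 100 degC matches exp(0.015 * 63)", {
  expect_lt(abs(exp(0.015 * 63) - 2.5728) / 2.5728, 5e-4)
})

test_that("thermal conductivity grows linearly and saturates at 100 degC", {
  expect_equal(thermal_conductivity(37, "cardiac"), 0.56)
  expect_equal(thermal_conductivity(100, "cardiac"), 0.6356, tolerance = 1e-12)
  expect_equal(thermal_conductivity(150, "cardiac"), 0.6356, tolerance = 1e-12)
  eps <- 1e-8
  expect_equal(thermal_conductivity(100 - eps, "cardiac"),
               thermal_conductivity(100 + eps, "cardiac"), tolerance = 1e-9)
  expect_equal(thermal_conductivity(60, "blood"), 0.52 + 0.0012 * 23)
})

test_that("effective heat capacity is the enthalpy derivative with the latent band", {
  expect_equal(effective_heat_capacity(50, "cardiac"), 1081 * 3686)
  expect_equal(effective_heat_capacity(99.5, "cardiac"), 2.162e9)
  expect_equal(effective_heat_capacity(120, "cardiac"), 370 * 2155.92)
  expect_equal(effective_heat_capacity(80, "blood"), 1050 * 3617)
  # enthalpy is nondecreasing and consistent with its derivative
  T <- seq(37, 140, by = 0.25)
  H <- material_enthalpy(T, "cardiac")
  expect_true(all(diff(H) > 0))
  mid <- (T[-1] + T[-length(T)]) / 2
  expect_equal(diff(H) / diff(T), effective_heat_capacity(mid, "cardiac"),
               tolerance = 1e-9)
})

test_that("material table carries the per-modality baselines", {
  rfa <- material_table("RFA"); pfa <- material_table("PFA")
  expect_equal(rfa["cardiac", "sigma0"], 0.281)
  expect_equal(pfa["cardiac", "sigma0"], 0.228)
  expect_equal(pfa["blood", "sigma0"], 0.706)
  expect_false("sensor" %in% pfa$material)   # sensor exists only in RFA models
  expect_equal(rfa["sensor", "k0"], 0.038)
  expect_equal(rfa["cardiac_vapor", "rho"], 370)
})
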