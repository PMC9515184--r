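test_that("Arrhenius damage matches the constant-temperature closed form", {
  cst <- constitutive_params()
  rate37 <- cst$arr_A * exp(-cst$arr_dE / (cst$gas_R * 310.15))
  d <- arrhenius_damage(seq(0, 30, by = 0.1), rep(37, 301))
  expect_equal(d$omega, 30 * rate37, tolerance = 1e-6)
  expect_lt(d$omega, 1e-2)
  # time to Omega = 1 at 100 degC is on the order of a millisecond
  t_1 <- 1 / arrhenius_rate(100)
  expect_gt(t_1, 1e-4); expect_lt(t_1, 1e-2)
  # Omega = 1 maps to 63.2 % damage probability
  expect_equal(100 * (1 - exp(-1)), 63.2, tolerance = 1e-3)
  d1 <- arrhenius_damage(c(0, t_1), rep(100, 2))
  expect_equal(d1$probability, 63.2, tolerance = 0.1)
  expect_error(arrhenius_damage(c(0, 2, 1), rep(37, 3)), "increasing")
})

test_that("damage is additive over concatenated histories", {
  t1 <- seq(0, 5, by = 0.05); t2 <- seq(5, 12, by = 0.05)
  Th <- function(t) 60 + 20 * sin(t / 2)
  full <- arrhenius_damage(c(t1, t2[-1]), Th(c(t1, t2[-1])))
  a <- arrhenius_damage(t1, Th(t1)); b <- arrhenius_damage(t2, Th(t2))
  expect_equal(full$omega, a$omega + b$omega, tolerance = 1e-12)
})

test_that("a hemispherical analytic field yields the closed-form lesion", {
  fx <- make_analytic_fixture("hemisphere_electrode", level = 1)
  m <- fx$mesh
  E_th <- 2e5                     # 2000 V/cm, inside the refined shell
  r_th <- fx$analytic$lesion_radius(E_th)
  # dense radial evaluation confirms the closed-form radius
  rr <- seq(r_th * 0.5, r_th * 2, length.out = 2001)
  E_r <- fx$params$V0 * fx$params$a / rr^2
  expect_equal(rr[which.min(abs(E_r - E_th))], r_th, tolerance = 1e-3)

  f <- fx$analytic$E_mag(m$nodes)
  m$region <- rep("cardiac", nrow(m$elems))   # whole half-space is tissue
  reg <- extract_lesion_region(m, f, E_th)
  mt <- lesion_metrics(reg, geometry = NULL)
  expect_equal(mt$V_mm3, 2 / 3 * pi * (r_th * 1e3)^3, tolerance = 0.03)
  expect_equal(mt$depth_mm, r_th * 1e3, tolerance = 0.02)
  expect_equal(mt$width_mm, 2 * r_th * 1e3, tolerance = 0.02)
  expect_equal(mt$sr[1] + mt$sr[2], 100, tolerance = 1e-9)
  expect_equal(mt$sr[1], 50, tolerance = 0.5)
})

test_that("a hemispherical region centred on the split plane measures exactly", {
  fx <- make_analytic_fixture("hemisphere_electrode", level = 1)
  m <- fx$mesh
  m$region <- rep("cardiac", nrow(m$elems))
  r0 <- 3e-3
  f <- 1 - sqrt(rowSums(m$nodes^2)) / r0     # >= 0 inside radius 3 mm
  mt <- lesion_metrics(extract_lesion_region(m, f, 0), geometry = NULL)
  expect_equal(mt$V_mm3, 56.55, tolerance = 0.03 * 56.55)
  expect_equal(mt$depth_mm, 3, tolerance = 0.02)
  expect_equal(mt$width_mm, 6, tolerance = 0.02 * 6)
  expect_equal(mt$sr, c(50, 50), tolerance = 0.5)
})

test_that("raising the threshold never grows the lesion", {
  ref <- pfa_mono_reference()
  f <- lesion_field_vcm_t(ref$mesh, ref$fs$E_elem)
  ths <- c(800, 1000, 1200, 1500)
  mts <- lapply(ths, function(th)
    lesion_metrics(extract_lesion_region(ref$mesh, f, th)))
  V <- vapply(mts, `[[`, numeric(1), "V_mm3")
  D <- vapply(mts, `[[`, numeric(1), "depth_mm")
  W <- vapply(mts, `[[`, numeric(1), "width_mm")
  expect_true(all(diff(V) < 0))
  expect_true(all(diff(D) <= 0))
  expect_true(all(diff(W) <= 0))
  for (mt in mts) expect_equal(mt$sr[1] + mt$sr[2], 100, tolerance = 1e-9)
})

test_that("empty regions give all-zero metrics", {
  fx <- make_analytic_fixture("uniform_plates")
  m <- fx$mesh
  m$region <- rep("cardiac", nrow(m$elems))
  mt <- lesion_metrics(extract_lesion_region(m, rep(0.4, m$n_nodes), 1),
                       geometry = NULL)
  expect_equal(mt$V_mm3, 0)
  expect_equal(mt$depth_mm, 0)
  expect_equal(mt$width_mm, 0)
})

test_that("lesions are confined to tissue regions", {
  ref <- pfa_mono_reference()
  f <- lesion_field_vcm_t(ref$mesh, ref$fs$E_elem)
  reg <- extract_lesion_region(ref$mesh, f, 1000)
  expect_true(all(ref$mesh$region[reg$elements] %in% c("cardiac", "skeletal")))
})
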