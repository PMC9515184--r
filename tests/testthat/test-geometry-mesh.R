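test_that("geometry construction matches the reference dimensions", {
  cfg <- scenario_config("PFA", "monopolar")
  g <- build_geometry(cfg)
  expect_equal(g$slab$X, 0.08); expect_equal(g$slab$Y, 0.08)
  expect_equal(g$slab$z_blood, 0.04)
  expect_equal(g$slab$z_cardiac, 0.02)
  expect_equal(g$slab$z_skeletal, 0.06)
  expect_equal(g$catheter$radius, 2.33e-3 / 2)
  expect_equal(g$catheter$D_E, 1.25e-3)
  # deepest catheter point sits exactly at the insertion depth
  expect_equal(g$catheter$base[3] - g$catheter$radius, -1.25e-3)

  gb <- build_geometry(scenario_config("PFA", "bipolar"))
  expect_equal(gb$catheter$D_E, 0.5e-3)
  expect_equal(gb$catheter$axis, c(1, 0, 0))      # horizontal, flow-aligned
  expect_equal(length(gb$catheter$electrodes), 4)
  pol <- vapply(gb$catheter$electrodes, `[[`, numeric(1), "polarity")
  expect_equal(pol, c(1, 0, 1, 0))                # alternating polarity

  expect_error(scenario_config("RFA", alpha_deg = 75), "alpha")
  expect_error(scenario_config("RFA", beta_deg = 30, half_domain = TRUE),
               "mirror-symmetric")
  expect_error(scenario_config("RFA", inlet_velocity = 0.5), "inlet_velocity")
})

test_that("tilting rotates the catheter about the contact point at fixed insertion", {
  g <- build_geometry(scenario_config("PFA", "monopolar", alpha_deg = 60))
  a <- g$catheter$axis
  expect_equal(acos(a[3]) * 180 / pi, 60, tolerance = 1e-9)
  # lowest point of the tilted catheter still at -D_E
  expect_equal(g$catheter$base[3] - g$catheter$radius, -1.25e-3)
})

test_that("mesh region volumes audit against analytic geometry volumes", {
  cfg <- scenario_config("PFA", "monopolar", mesh_resolution = "coarse")
  g <- build_geometry(cfg)
  m <- generate_mesh(g)
  v <- mesh_region_volumes(m)
  # exact partition of the domain
  expect_equal(sum(m$vol), 0.08 * 0.08 * 0.12, tolerance = 1e-3 * 1e-3)
  # analytic layer volumes minus the submerged / immersed catheter parts
  r <- g$catheter$radius; zc <- g$catheter$base[3]
  v_sub <- 2 / 3 * pi * r^3 + pi * r^2 * (-zc)       # below z = 0
  cath_len_blood <- g$catheter$s_max - 0             # axis above base, alpha = 0
  v_blood_cath <- pi * r^2 * cath_len_blood - (pi * r^2 * (-zc) + 2 / 3 * pi * r^3) +
    pi * r^2 * 0                                      # catheter volume above z=0
  v_cath_total <- pi * r^2 * (g$catheter$s_max - g$catheter$s_min) + 2 / 3 * pi * r^3
  expect_equal(unname(v["cardiac"]), 0.08 * 0.08 * 0.02 - v_sub,
               tolerance = 0.01)
  expect_equal(unname(v["skeletal"]), 0.08 * 0.08 * 0.06, tolerance = 0.01)
  expect_equal(unname(v["blood"]), 0.08 * 0.08 * 0.04 - (v_cath_total - v_sub),
               tolerance = 0.01)
  # catheter body resolved within a quarter of its true volume at coarse core
  vc <- sum(v[c("electrode", "insulation")])
  expect_lt(abs(vc - v_cath_total) / v_cath_total, 0.25)
})

test_that("the paper-resolution monopolar mesh hits the published element budget", {
  cfg <- scenario_config("PFA", "monopolar", mesh_resolution = "paper")
  m <- generate_mesh(build_geometry(cfg))
  expect_gte(m$n_elems, 23000)
  expect_lte(m$n_elems, 92000)
})

test_that("element quality does not collapse under refinement", {
  floor_q <- 0.005   # graded tensor meshes keep deliberately anisotropic far-field cells
  qs <- sapply(c("paper", "coarse", "medium"), function(res) {
    cfg <- scenario_config("PFA", "monopolar", mesh_resolution = res,
                           half_domain = TRUE)
    min(mesh_quality(generate_mesh(build_geometry(cfg))))
  })
  expect_true(all(qs > floor_q))
})

test_that("half-domain meshes mirror onto the full symmetric mesh", {
  cfg_h <- scenario_config("PFA", "monopolar", mesh_resolution = "paper",
                           half_domain = TRUE)
  cfg_f <- scenario_config("PFA", "monopolar", mesh_resolution = "paper")
  mh <- generate_mesh(build_geometry(cfg_h))
  mf <- generate_mesh(build_geometry(cfg_f))
  key <- function(nd) paste(round(nd[, 1], 12), round(abs(nd[, 2]), 12),
                            round(nd[, 3], 12))
  expect_true(setequal(key(mh$nodes), key(mf$nodes)))
})

test_that("every element carries exactly one region and electrodes are tagged", {
  m <- pfa_mono_small_mesh()
  expect_true(all(m$region %in% c("blood", "cardiac", "skeletal", "electrode",
                                  "electrode_gnd", "insulation", "sensor")))
  expect_gt(length(m$active_nodes), 0)
  expect_gt(length(m$ground_nodes), 0)
  # RFA meshes have sensor nodes inside the electrode body
  cfgr <- scenario_config("RFA", "monopolar", mesh_resolution = "coarse",
                          half_domain = TRUE)
  mr <- generate_mesh(build_geometry(cfgr))
  expect_gt(length(mr$sensor_nodes), 0)
})

test_that("scenario configs round-trip through YAML", {
  cfg <- scenario_config("PFA", "bipolar", inlet_velocity = 0.03,
                         alpha_deg = 0, applied_voltage = 1400,
                         mesh_resolution = "medium")
  path <- tempfile(fileext = ".yaml")
  write_scenario(cfg, path)
  cfg2 <- read_scenario(path)
  expect_equal(cfg2, cfg)
})

test_that("meshes round-trip through legacy VTK exactly", {
  fx <- make_analytic_fixture("uniform_plates")
  path <- tempfile(fileext = ".vtk")
  write_vtk_mesh(fx$mesh, path, point_data = list(z = fx$mesh$nodes[, 3]))
  back <- read_vtk_mesh(path)
  expect_identical(back$elems, fx$mesh$elems)
  expect_equal(back$nodes, fx$mesh$nodes, tolerance = 0)
  expect_equal(back$point_data$z, fx$mesh$nodes[, 3], tolerance = 0)
})
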