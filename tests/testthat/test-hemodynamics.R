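test_that("zero inflow yields the null flow solution", {
  m <- pfa_mono_small_mesh()
  ff <- solve_stationary_flow(m, 0)
  expect_equal(max(abs(ff$u)), 0)
  expect_equal(max(abs(ff$p)), 0)
  expect_true(ff$converged)
})

test_that("plane Poiseuille flow develops the 3:2 peak-to-mean ratio", {
  fx <- make_analytic_fixture("poiseuille_channel")
  m <- fx$mesh
  ff <- solve_stationary_flow(m, 0.001, max_iter = 40)
  expect_true(ff$converged)
  H <- fx$params$H; L <- fx$params$L; W <- fx$params$W
  sel <- which(abs(m$nodes[, 1] - 0.75 * L) < 1e-9 &
               abs(m$nodes[, 2] - W / 2) < 1e-9)
  z <- m$nodes[sel, 3]; u <- ff$u[sel, 1]
  o <- order(z)
  u_mean <- sum(diff(z[o]) * (u[o][-1] + u[o][-length(u)]) / 2) / H
  expect_equal(max(u) / u_mean, 1.5, tolerance = 0.02)
})

test_that("chamber flow balances mass and decelerates in the catheter wake", {
  run <- rfa_mono_reference()
  ff <- run$flow
  expect_lt(abs(ff$flux_in + ff$flux_out) / abs(ff$flux_in), 1e-3)
  nd <- run$mesh$nodes
  spd <- sqrt(rowSums(ff$u^2))
  band <- abs(nd[, 2]) < 5e-3 & nd[, 3] > 0.5e-3 & nd[, 3] < 8e-3
  up <- band & nd[, 1] > -15e-3 & nd[, 1] < -3e-3
  dn <- band & nd[, 1] > 3e-3 & nd[, 1] < 15e-3
  # speeds exceed the inlet value upstream of the catheter and drop in its wake
  expect_gt(max(spd[up]), 0.06)
  expect_lt(mean(spd[dn]), mean(spd[up]))
})

test_that("creeping flow responds linearly to the inlet velocity", {
  fx <- make_analytic_fixture("poiseuille_channel")
  f1 <- solve_stationary_flow(fx$mesh, 2e-4, tol = 1e-8, max_iter = 60)
  f2 <- solve_stationary_flow(fx$mesh, 1e-4, tol = 1e-8, max_iter = 60)
  expect_lt(max(abs(f1$u / 2 - f2$u)) / max(abs(f2$u)), 0.02)
})

test_that("the flow field is mirror-symmetric for the symmetric geometry", {
  # probed in the stable laminar regime: at transitional Re the wake behind
  # the catheter amplifies the O(h) chirality of the tetrahedral splitting
  U <- 0.002
  cfg <- scenario_config("RFA", "monopolar", inlet_velocity = U,
                         mesh_resolution = "paper")
  m <- generate_mesh(build_geometry(cfg))
  ff <- suppressWarnings(solve_stationary_flow(m, U, tol = 1e-6,
                                               max_iter = 30))
  nd <- round(m$nodes, 12)
  key <- paste(nd[, 1], nd[, 2], nd[, 3])
  mirror_key <- paste(nd[, 1], -nd[, 2], nd[, 3])
  idx <- match(mirror_key, key)
  ok <- !is.na(idx)
  du <- ff$u[ok, ] - ff$u[idx[ok], ] %*% diag(c(1, -1, 1))
  expect_lt(max(abs(du)), 0.01 * U)   # within 1 % of the inlet speed
})
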