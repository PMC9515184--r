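# Analytic verification fixtures: small meshes paired with closed-form
# solutions, used to verify the electric, thermal and flow solvers against
# independent oracles.

#' Analytic verification fixture
#'
#' Builds a small mesh together with a closed-form reference solution:
#'
#' * `uniform_plates`: a slab of thickness `d` between two full-face plate
#'   electrodes at `V0` and ground; `Phi` is linear and `|E| = V0/d`
#'   everywhere.
#' * `hemisphere_electrode`: a hemispherical electrode of radius `a` at `V0`
#'   on a uniform conductive half-space; `Phi(r) = V0 a / r`,
#'   `|E|(r) = V0 a / r^2`. The truncated far boundary carries the analytic
#'   potential so the only error is discretization.
#' * `slab_conduction_1d`: semi-infinite solid at 37 degC whose surface is
#'   stepped to `T_s`; `T(x,t) = 37 + (T_s - 37) erfc(x / (2 sqrt(kappa t)))`.
#' * `poiseuille_channel`: pressure-driven laminar flow between parallel
#'   plates (slip lateral walls); the developed profile is parabolic with
#'   peak velocity 1.5 times the mean.
#'
#' @param name fixture name (see above).
#' @param level integer refinement level (>= 1); spacings scale as `1/level`.
#' @return an object of class `ablation_fixture` with elements `name`,
#'   `mesh`, `params` and `analytic` (closed-form evaluators).
#' @export
make_analytic_fixture <- function(name = c("uniform_plates", "hemisphere_electrode",
                                           "slab_conduction_1d", "poiseuille_channel"),
                                  level = 1) {
  name <- match.arg(name)
  stopifnot(level >= 1)
  fx <- switch(name,
    uniform_plates = .fixture_plates(level),
    hemisphere_electrode = .fixture_hemisphere(level),
    slab_conduction_1d = .fixture_slab1d(level),
    poiseuille_channel = .fixture_poiseuille(level))
  fx$name <- name
  fx$level <- level
  class(fx) <- "ablation_fixture"
  fx
}

.fixture_mesh <- function(xs, ys, zs, region = "cardiac") {
  m <- .tensor_tet_mesh(xs, ys, zs)
  m$region <- rep(region, nrow(m$elems))
  m$axes <- list(x = xs, y = ys, z = zs)
  m$half_domain <- FALSE
  class(m) <- "ablation_mesh"
  m
}

.fixture_plates <- function(level) {
  d <- 2e-3; w <- 4e-3
  n <- 4L * level
  m <- .fixture_mesh(seq(0, w, length.out = n + 1),
                     seq(0, w, length.out = n + 1),
                     seq(0, d, length.out = n + 1))
  tol <- 1e-12
  m$active_nodes <- which(abs(m$nodes[, 3] - d) < tol)
  m$ground_nodes <- which(abs(m$nodes[, 3]) < tol)
  V0 <- 10
  list(mesh = m, params = list(V0 = V0, d = d),
       analytic = list(
         phi = function(p) V0 * p[, 3] / d,
         E_mag = function(p) rep(V0 / d, nrow(p))))
}

.fixture_hemisphere <- function(level) {
  a <- 1e-3; L <- 16e-3; V0 <- 1000
  h0 <- 0.25e-3 / level
  ax <- .axis_coords(0, L, bands = list(list(a = 0, b = 2 * a, h = h0)),
                     h_max = 3e-3, slope = 0.5)
  xs <- .mirror_axis(ax)
  zs <- -rev(ax)
  m <- .fixture_mesh(xs, xs, zs)
  r <- sqrt(rowSums(m$nodes^2))
  # the electrode is represented by a thin node shell r <= 1.2 a carrying the
  # exact potential (V0 on r <= a), so the measured error is discretization
  # of the harmonic far field, not staircasing of the spherical surface
  m$active_nodes <- which(r <= 1.2 * a + 1e-9)
  outer <- which(abs(m$nodes[, 1]) > L - 1e-9 | abs(m$nodes[, 2]) > L - 1e-9 |
                 m$nodes[, 3] < -L + 1e-9)
  m$ground_nodes <- setdiff(outer, m$active_nodes)
  phi_fun <- function(p) {
    rr <- pmax(sqrt(rowSums(p^2)), a)
    V0 * a / rr
  }
  list(mesh = m,
       params = list(a = a, V0 = V0, L = L,
                     active_values = phi_fun(m$nodes[m$active_nodes, , drop = FALSE]),
                     outer_values = phi_fun(m$nodes[setdiff(outer, m$active_nodes), ,
                                                    drop = FALSE])),
       analytic = list(
         phi = phi_fun,
         E_mag = function(p) {
           rr <- pmax(sqrt(rowSums(p^2)), a)
           V0 * a / rr^2
         },
         lesion_radius = function(E_th_vm) sqrt(V0 * a / E_th_vm)))
}

.fixture_slab1d <- function(level) {
  Lbar <- 15e-3
  h0 <- 0.3e-3 / level
  xs <- .axis_coords(0, Lbar, bands = list(list(a = 0, b = 2e-3, h = h0)),
                     h_max = 1.5e-3, slope = 0.4)
  yz <- seq(0, 1e-3, length.out = 3)
  m <- .fixture_mesh(xs, yz, yz)
  tol <- 1e-12
  k <- 0.56; rhoc <- 1081 * 3686
  kappa <- k / rhoc
  T_s <- 60
  list(mesh = m,
       params = list(k = k, rhoc = rhoc, kappa = kappa, T_s = T_s, L = Lbar,
                     surface_nodes = which(abs(m$nodes[, 1]) < tol),
                     far_nodes = which(abs(m$nodes[, 1] - Lbar) < tol)),
       analytic = list(
         T = function(x, t) 37 + (T_s - 37) *
           .erfc(x / (2 * sqrt(kappa * t)))))
}

.erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

.fixture_poiseuille <- function(level) {
  H <- 2e-3; L <- 12e-3; W <- 0.5e-3
  nz <- 8L * level                      # even: grid node on the mid-plane
  h <- H / nz                           # near-isotropic cells
  m <- .fixture_mesh(seq(0, L, by = h),
                     seq(0, W, length.out = 3),
                     seq(0, H, length.out = nz + 1))
  tol <- 1e-12
  nd <- m$nodes
  m$flow_bc <- list(
    inlet  = which(abs(nd[, 1]) < tol),
    outlet = which(abs(nd[, 1] - L) < tol),
    noslip = which(abs(nd[, 3]) < tol | abs(nd[, 3] - H) < tol),
    slip_y = which(abs(nd[, 2]) < tol | abs(nd[, 2] - W) < tol))
  list(mesh = m, params = list(H = H, L = L, W = W, ratio_peak_mean = 1.5),
       analytic = list(
         u_profile = function(z, u_mean) 6 * u_mean * (z / H) * (1 - z / H)))
}
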