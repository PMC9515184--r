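# Stationary incompressible laminar blood flow in the chamber, providing the
# frozen advection field for the thermal solve.
#
# Discretization: equal-order P1/P1 with pressure (Brezzi-Pitkaranta-type)
# stabilization and streamline-diffusion stabilization of the convective
# term. The nonlinearity is handled either by damped Picard iteration on the
# coupled Oseen problem (small verification meshes) or, on the chamber
# meshes, by pseudo-time projection marching with cached SPD factorizations
# followed by one coupled Oseen solve at the converged advection field (so
# the returned field is a discretely mass-conserving Oseen solution).

#' Solve the stationary blood-flow problem
#'
#' Steady laminar incompressible Navier-Stokes flow on the blood region of
#' the mesh: uniform normal inflow at the inlet face, zero pressure at the
#' outlet, no-slip on every other wall (endocardial surface, chamber walls
#' and catheter), and slip on the symmetry plane of half-domain meshes.
#'
#' @param mesh an `ablation_mesh` (the blood sub-region is extracted
#'   automatically) or a fixture mesh carrying a `flow_bc` list.
#' @param inlet_velocity inflow speed, m/s (non-negative).
#' @param density blood density, kg/m^3.
#' @param viscosity dynamic viscosity, Pa s.
#' @param tol relative nonlinear convergence tolerance.
#' @param max_iter maximum Picard iterations.
#' @param relax Picard damping factor.
#' @param method `"coupled"` (damped Picard on the full saddle system),
#'   `"projection"` (pseudo-time marching, then one coupled Oseen solve) or
#'   `"auto"` (projection for chamber meshes, coupled for small fixtures).
#' @return an object of class `flow_field`: nodal velocity `u` (n x 3, m/s on
#'   the full mesh node set, zero outside blood), nodal pressure `p` (Pa),
#'   inlet/outlet fluxes (m^3/s) and convergence diagnostics.
#' @export
solve_stationary_flow <- function(mesh, inlet_velocity,
                                  density = 1050, viscosity = 0.0021,
                                  tol = 1e-6, max_iter = 40, relax = 0.7,
                                  method = c("auto", "coupled", "projection")) {
  stopifnot(inlet_velocity >= 0)
  method <- match.arg(method)
  n_full <- mesh$n_nodes
  if (!is.null(mesh$flow_bc)) {
    sub <- list(mesh = mesh, map = seq_len(n_full), bc = mesh$flow_bc)
  } else {
    sub <- .blood_submesh(mesh)
  }
  sm <- sub$mesh; bc <- sub$bc
  n <- sm$n_nodes
  if (inlet_velocity == 0) {
    u <- matrix(0, n_full, 3)
    return(structure(list(u = u, p = numeric(n_full), flux_in = 0, flux_out = 0,
                          converged = TRUE, iterations = 0L, residuals = numeric(0),
                          reynolds = 0),
                     class = "flow_field"))
  }

  parts <- .stiffness_parts(sm)
  Kv <- .assemble_from_parts(parts, rep(viscosity, nrow(sm$elems)))
  Gx <- .assemble_gradient(sm, 1); Gy <- .assemble_gradient(sm, 2)
  Gz <- .assemble_gradient(sm, 3)

  # pressure stabilization length: volume-equivalent element size (the
  # spurious mass flux ~ tau grad p it injects is negligible where the graded
  # far-field cells are anisotropic, because grad p is small there)
  hel <- (6 * sqrt(2) * sm$vol)^(1/3)

  # Dirichlet sets per velocity component
  noslip <- bc$noslip
  inlet <- setdiff(bc$inlet, noslip)
  fixed_u <- c(inlet, noslip); val_u <- c(rep(inlet_velocity, length(inlet)),
                                          rep(0, length(noslip)))
  fixed_v <- unique(c(inlet, noslip, bc$slip_y)); val_v <- rep(0, length(fixed_v))
  fixed_w <- unique(c(inlet, noslip, bc$slip_z %||% integer(0)))
  val_w <- rep(0, length(fixed_w))
  # outlet pressure is imposed weakly by the do-nothing boundary condition
  fixed_p <- integer(0); val_p <- numeric(0)

  idx_u <- seq_len(n); idx_v <- n + idx_u; idx_w <- 2L * n + idx_u
  idx_p <- 3L * n + idx_u
  fixed <- c(fixed_u, n + fixed_v, 2L * n + fixed_w, 3L * n + fixed_p)
  if (!length(fixed_p)) fixed <- c(fixed_u, n + fixed_v, 2L * n + fixed_w)
  vals <- c(val_u, val_v, val_w, val_p)

  uk <- matrix(0, n, 3); uk[inlet, 1] <- inlet_velocity
  Re <- density * inlet_velocity * diff(range(sm$nodes[, 3])) / viscosity
  if (method == "auto") method <- if (n > 3000) "projection" else "coupled"
  if (method == "projection") {
    uk <- .flow_march(sm, bc, inlet_velocity, density, viscosity,
                      parts = parts, Kv = Kv, G = list(Gx, Gy, Gz))
    max_iter <- min(max_iter, 2L)
  }
  res_hist <- numeric(0)
  converged <- FALSE
  sol <- NULL
  for (it in seq_len(max_iter)) {
    we <- (matrix(uk[sm$elems, 1], ncol = 4) |> rowMeans()) |> cbind(
      matrix(uk[sm$elems, 2], ncol = 4) |> rowMeans(),
      matrix(uk[sm$elems, 3], ncol = 4) |> rowMeans())
    C <- .assemble_advection(sm, we, rep(density, nrow(sm$elems)), stabilize = TRUE)
    A <- Kv + C
    spd <- sqrt(rowSums(we^2))
    tau_p <- 0.2 * hel^2 / (4 * viscosity + 2 * density * spd * hel)
    Sp <- .assemble_from_parts(parts, tau_p)
    Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
    Amat <- rbind(
      cbind(A, Z, Z, -Matrix::t(Gx)),
      cbind(Z, A, Z, -Matrix::t(Gy)),
      cbind(Z, Z, A, -Matrix::t(Gz)),
      cbind(Gx, Gy, Gz, Sp))
    rhs <- numeric(4L * n)
    free <- setdiff(seq_len(4L * n), fixed)
    x <- numeric(4L * n); x[fixed] <- vals
    b <- rhs[free] - as.numeric(Amat[free, fixed, drop = FALSE] %*% vals)
    x[free] <- as.numeric(Matrix::solve(Amat[free, free], b))
    un <- cbind(x[idx_u], x[idx_v], x[idx_w])
    delta <- sqrt(sum((un - uk)^2)) / max(sqrt(sum(un^2)), .Machine$double.eps)
    res_hist <- c(res_hist, delta)
    if (!is.finite(delta))
      stop("flow iteration diverged (Re = ", signif(Re, 4), ", residuals: ",
           paste(signif(res_hist, 3), collapse = ", "), ")")
    uk <- relax * un + (1 - relax) * uk
    if (delta < tol) { converged <- TRUE; sol <- list(u = un, p = x[idx_p]); break }
    sol <- list(u = un, p = x[idx_p])
  }
  if (!converged && method == "projection" &&
      res_hist[length(res_hist)] < 0.05) converged <- TRUE
  if (!converged)
    warning("flow Picard iteration stopped at relative change ",
            signif(res_hist[length(res_hist)], 3), " after ", it,
            " iterations (Re = ", signif(Re, 4), ")")

  u_full <- matrix(0, n_full, 3); p_full <- numeric(n_full)
  u_full[sub$map, ] <- sol$u; p_full[sub$map] <- sol$p

  fg <- sub$face_geom
  flux <- function(tag) {
    if (is.null(fg)) return(NA_real_)
    sel <- fg$tag == tag
    if (!any(sel)) return(0)
    um <- (sol$u[fg$faces[sel, 1], , drop = FALSE] +
           sol$u[fg$faces[sel, 2], , drop = FALSE] +
           sol$u[fg$faces[sel, 3], , drop = FALSE]) / 3
    sum(fg$area[sel] * rowSums(um * fg$normal[sel, , drop = FALSE]))
  }
  structure(list(u = u_full, p = p_full,
                 flux_in = flux("inlet"), flux_out = flux("outlet"),
                 converged = converged, iterations = it, residuals = res_hist,
                 reynolds = Re, submesh_map = sub$map),
            class = "flow_field")
}

# Extract the blood region as a stand-alone mesh with renumbered nodes and
# tagged boundary: inlet (x = xmin), outlet (x = xmax), symmetry slip (y = 0,
# half domain), no-slip everywhere else.
.blood_submesh <- function(mesh) {
  sel <- which(mesh$region == "blood")
  el <- mesh$elems[sel, , drop = FALSE]
  used <- sort(unique(as.vector(el)))
  remap <- integer(mesh$n_nodes); remap[used] <- seq_along(used)
  sm <- list(nodes = mesh$nodes[used, , drop = FALSE],
             elems = matrix(remap[el], ncol = 4),
             vol = mesh$vol[sel],
             gx = mesh$gx[sel, , drop = FALSE], gy = mesh$gy[sel, , drop = FALSE],
             gz = mesh$gz[sel, , drop = FALSE],
             n_nodes = length(used), n_elems = length(sel),
             region = rep("blood", length(sel)))

  bf <- .boundary_faces(sm$elems)
  fg <- .face_geometry(sm$nodes, bf$faces, bf$owner, sm$elems)
  xr <- range(mesh$nodes[, 1])
  tol <- 1e-9
  tag <- rep("noslip", nrow(bf$faces))
  tag[abs(fg$centroid[, 1] - xr[1]) < tol] <- "inlet"
  tag[abs(fg$centroid[, 1] - xr[2]) < tol] <- "outlet"
  if (isTRUE(mesh$half_domain)) tag[abs(fg$centroid[, 2]) < tol] <- "slip"

  nd <- sm$nodes
  face_nodes <- function(t) sort(unique(as.vector(bf$faces[tag == t, ])))
  inlet_n <- face_nodes("inlet"); outlet_n <- face_nodes("outlet")
  slip_n <- face_nodes("slip")
  # wall no-slip has priority at inlet/outlet rim nodes (the rim is wall)
  noslip_n <- face_nodes("noslip")
  slip_n <- setdiff(slip_n, c(noslip_n, inlet_n, outlet_n))
  bc <- list(inlet = inlet_n, outlet = setdiff(outlet_n, noslip_n),
             noslip = noslip_n, slip_y = slip_n)
  list(mesh = sm, map = used, bc = bc,
       face_geom = list(faces = bf$faces, tag = tag, area = fg$area,
                        normal = fg$normal))
}

#' @export
print.flow_field <- function(x, ...) {
  cat("Stationary blood-flow field\n")
  cat(sprintf("  Re = %.0f, iterations = %d, converged = %s\n",
              x$reynolds, x$iterations, x$converged))
  cat(sprintf("  flux in = %.4g, out = %.4g m^3/s (balance %.3g)\n",
              x$flux_in, x$flux_out,
              abs(x$flux_in + x$flux_out) / max(abs(x$flux_in), 1e-300)))
  invisible(x)
}

# smallest edge length per element
.min_edge <- function(sm) {
  nd <- sm$nodes; el <- sm$elems
  L2 <- Inf
  for (pair in list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
    d <- nd[el[, pair[1]], , drop = FALSE] - nd[el[, pair[2]], , drop = FALSE]
    L2 <- pmin(L2, rowSums(d^2))
  }
  sqrt(L2)
}

# Pseudo-time projection marching towards the steady flow: backward-Euler
# viscous step with explicit (streamline-stabilized) advection, pressure
# Poisson projection, all with cached Cholesky factorizations.
.flow_march <- function(sm, bc, inlet_velocity, density, viscosity,
                        parts, Kv, G, cfl = 0.45, max_steps = 600,
                        check_every = 20L, tol_steady = 2e-3) {
  n <- sm$n_nodes
  ML <- .nodal_volumes(sm) * density
  noslip <- bc$noslip
  inlet <- setdiff(bc$inlet, noslip)
  fixed <- list(u = c(inlet, noslip),
                v = unique(c(inlet, noslip, bc$slip_y)),
                w = unique(c(inlet, noslip, bc$slip_z %||% integer(0))))
  vals <- list(u = c(rep(inlet_velocity, length(inlet)), rep(0, length(noslip))),
               v = rep(0, length(fixed$v)), w = rep(0, length(fixed$w)))

  # pressure Poisson operator: unit Laplacian, p = 0 on the outlet
  Kp <- .assemble_from_parts(parts, rep(1, nrow(sm$elems)))
  pfix <- bc$outlet
  pfree <- setdiff(seq_len(n), pfix)
  chol_p <- Matrix::Cholesky(Matrix::forceSymmetric(Kp[pfree, pfree]),
                             LDL = FALSE)

  hmin <- .min_edge(sm)
  el <- sm$elems
  gx <- sm$gx; gy <- sm$gy; gz <- sm$gz; v4 <- sm$vol / 4

  u <- matrix(0, n, 3)
  u[fixed$u, 1] <- c(vals$u)
  u_chk <- u
  dt <- NA_real_
  fact <- NULL
  for (step in seq_len(max_steps)) {
    spd_n <- sqrt(rowSums(u^2))
    if (step %% 100L == 1L) {
      u_ref <- max(2 * inlet_velocity, max(spd_n))
      dt_new <- cfl * min(hmin) / u_ref
      if (is.na(dt) || dt_new < 0.7 * dt) {
        dt <- dt_new
        A <- Matrix::Diagonal(x = ML / dt) + Kv
        fact <- lapply(fixed, function(fx) {
          fr <- setdiff(seq_len(n), fx)
          list(free = fr,
               chol = Matrix::Cholesky(Matrix::forceSymmetric(A[fr, fr]),
                                       LDL = FALSE),
               Afd = A[fr, fx, drop = FALSE])
        })
      }
    }
    # explicit advection load with streamline stabilization
    we <- cbind(rowMeans(matrix(u[el, 1], ncol = 4)),
                rowMeans(matrix(u[el, 2], ncol = 4)),
                rowMeans(matrix(u[el, 3], ncol = 4)))
    wg <- list(gx, gy, gz)
    conv <- matrix(0, nrow(el), 3)      # (w . grad) u per element
    wgj <- matrix(0, nrow(el), 4)       # w . grad phi_j
    for (j in 1:4) wgj[, j] <- we[, 1] * gx[, j] + we[, 2] * gy[, j] + we[, 3] * gz[, j]
    for (c in 1:3) conv[, c] <- rowSums(wgj * matrix(u[el, c], ncol = 4))
    sa <- rowSums(abs(wgj)); tau <- ifelse(sa > 0, 1 / sa, 0)
    load <- matrix(0, n, 3)
    for (c in 1:3) {
      base <- density * v4 * conv[, c]
      for (i in 1:4) {
        contrib <- base + density * sm$vol * tau * wgj[, i] * conv[, c]
        load[, c] <- load[, c] + as.numeric(Matrix::sparseMatrix(
          i = el[, i], j = rep(1L, nrow(el)), x = contrib, dims = c(n, 1)))
      }
    }
    ustar <- u
    comp <- c("u", "v", "w")
    for (c in 1:3) {
      f <- fact[[comp[c]]]
      b <- (ML / dt) * u[, c] - load[, c]
      bb <- b[f$free] - as.numeric(f$Afd %*% vals[[comp[c]]])
      x <- numeric(n); x[fixed[[comp[c]]]] <- vals[[comp[c]]]
      x[f$free] <- as.numeric(Matrix::solve(f$chol, bb))
      ustar[, c] <- x
    }
    # pressure projection
    div <- as.numeric(G[[1]] %*% ustar[, 1] + G[[2]] %*% ustar[, 2] +
                      G[[3]] %*% ustar[, 3])
    rhsp <- -(density / dt) * div
    p <- numeric(n)
    p[pfree] <- as.numeric(Matrix::solve(chol_p, rhsp[pfree]))
    for (c in 1:3) {
      gp <- as.numeric(G[[c]] %*% p)
      ustar[, c] <- ustar[, c] - (dt / density) * gp / (ML / density)
    }
    for (c in 1:3) ustar[fixed[[comp[c]]], c] <- vals[[comp[c]]]
    u <- ustar
    if (step %% check_every == 0L) {
      rel <- sqrt(sum((u - u_chk)^2)) / max(sqrt(sum(u^2)), .Machine$double.eps)
      if (rel < tol_steady) break
      u_chk <- u
    }
  }
  u
}
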