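# Transient thermal solve: Pennes bioheat with Joule source, enthalpy phase
# change in cardiac tissue, and advection by the frozen blood-flow field.
#
# Time integration is operator-split backward Euler: blood advection is
# advanced explicitly with streamline-stabilized transport sub-steps (local
# CFL limited), then conduction with the Joule source is advanced implicitly
# with the SPD matrix Cap(T)/dt + K(k(T)), whose Cholesky factorization is
# reused across steps (numeric update on a cached symbolic analysis) and
# only rebuilt when the conductivity lag threshold is exceeded, dt changes,
# or nodes cross a heat-capacity segment of the enthalpy curve.

#' Joule heat source from a field solution
#'
#' Per-element volumetric power density `q = sigma |E|^2` (W/m^3), with
#' perfusion and metabolic terms identically zero.
#'
#' @param field a `field_solution`.
#' @return an object of class `heat_source` (list with element vector `q`).
#' @export
joule_source <- function(field) {
  structure(list(q = field$sigma * field$E_elem^2), class = "heat_source")
}

#' Create a transient thermal state
#'
#' Initialises the thermal model on a mesh: uniform 37 degC, exterior
#' boundaries clamped at 37 degC, optional advection by a stationary blood
#' flow field.
#'
#' @param mesh an `ablation_mesh` (or fixture mesh).
#' @param flow optional `flow_field` whose velocity advects heat in the blood
#'   region.
#' @param T0 initial temperature, degC.
#' @param dirichlet_nodes,dirichlet_values boundary override (default: all
#'   exterior nodes at 37 degC).
#' @param constant_properties logical; if `TRUE` the material laws are frozen
#'   at their baseline values (used by analytic verification fixtures).
#' @param k_lag rebuild threshold for the temperature-dependent conductivity
#'   matrix, degC.
#' @return an object of class `thermal_state` with nodal temperature `T`,
#'   running per-node maximum `T_max`, Arrhenius accumulator `omega` and
#'   simulation time `t`.
#' @export
thermal_state <- function(mesh, flow = NULL, T0 = 37,
                          dirichlet_nodes = NULL, dirichlet_values = NULL,
                          constant_properties = FALSE, k_lag = 2.0) {
  n <- mesh$n_nodes
  matmap <- c(blood = "blood", cardiac = "cardiac", skeletal = "skeletal",
              electrode = "electrode", electrode_gnd = "electrode",
              insulation = "insulation", sensor = "sensor")
  mat_elem <- unname(matmap[mesh$region])

  # lumped nodal volumes per material
  mats <- unique(mat_elem)
  Vn <- lapply(mats, function(mm) .nodal_volumes(mesh, which(mat_elem == mm)))
  names(Vn) <- mats
  cap_const <- numeric(n)
  for (mm in setdiff(mats, "cardiac")) {
    row <- .mat_row(mm, "RFA")
    cap_const <- cap_const + Vn[[mm]] * row$rho * row$cp
  }
  Vc <- if ("cardiac" %in% mats) Vn[["cardiac"]] else numeric(n)

  C_adv <- NULL
  if (!is.null(flow) && max(abs(flow$u)) > 0) {
    blood <- which(mesh$region == "blood")
    we <- cbind(rowMeans(matrix(flow$u[mesh$elems, 1], ncol = 4)),
                rowMeans(matrix(flow$u[mesh$elems, 2], ncol = 4)),
                rowMeans(matrix(flow$u[mesh$elems, 3], ncol = 4)))
    we[-blood, ] <- 0                 # advection only in the blood region
    rb <- .mat_row("blood", "RFA")
    C_adv <- .assemble_advection(mesh, we, rep(rb$rho * rb$cp, nrow(mesh$elems)),
                                 stabilize = TRUE)
    # local advective time-scale 1 / sum_i |u . grad phi_i| per element
    wg <- abs(we[, 1] * mesh$gx + we[, 2] * mesh$gy + we[, 3] * mesh$gz)
    sa <- rowSums(wg)
    dt_cfl <- 0.7 / max(sa[sa > 0])
  }

  if (is.null(dirichlet_nodes)) {
    dirichlet_nodes <- mesh$exterior_nodes %||% integer(0)
    dirichlet_values <- rep(37, length(dirichlet_nodes))
  }
  if (is.null(dirichlet_values)) dirichlet_values <- rep(37, length(dirichlet_nodes))

  model <- new.env(parent = emptyenv())
  model$mesh <- mesh
  model$parts <- .stiffness_parts(mesh)
  model$mat_elem <- mat_elem
  model$cap_const <- cap_const
  model$Vc <- Vc
  model$C_adv <- C_adv
  model$dt_cfl <- if (!is.null(C_adv)) dt_cfl else Inf
  model$fixed <- dirichlet_nodes
  model$fixed_vals <- dirichlet_values
  model$free <- setdiff(seq_len(n), dirichlet_nodes)
  model$const_props <- constant_properties
  model$k_lag <- k_lag
  model$Tk_ref <- NULL
  model$fact <- NULL
  model$dt_last <- NA_real_

  structure(list(T = rep(T0, n), T_max = rep(T0, n), omega = numeric(n),
                 t = 0, model = model), class = "thermal_state")
}

# element thermal conductivities at element-mean temperature
.k_map <- function(model, T_nodes) {
  mesh <- model$mesh
  Te <- rowMeans(matrix(T_nodes[mesh$elems], ncol = 4))
  k <- numeric(length(Te))
  for (mm in unique(model$mat_elem)) {
    sel <- model$mat_elem == mm
    k[sel] <- if (model$const_props) .mat_row(mm, "RFA")$k0
              else thermal_conductivity(Te[sel], mm)
  }
  k
}

# apparent volumetric heat capacity diagonal at the current temperature
.cap_diag <- function(model, T_nodes) {
  cap <- model$cap_const
  if (!any(model$Vc > 0)) return(cap)
  if (model$const_props) {
    rl <- .mat_row("cardiac", "RFA")
    return(cap + model$Vc * rl$rho * rl$cp)
  }
  cap + model$Vc * effective_heat_capacity(T_nodes, "cardiac")
}

# Piecewise-linear nodal enthalpy (relative to 37 degC) and its inverse. Each
# node mixes a constant-capacity part (cap_const) with the cardiac
# phase-change enthalpy weighted by its cardiac nodal volume.
.node_enthalpy <- function(model, T) {
  model$cap_const * (T - 37) + model$Vc * material_enthalpy(T, "cardiac")
}

.node_enthalpy_inverse <- function(model, H) {
  cst <- .ablatr_const
  rl <- .mat_row("cardiac", "RFA"); rv <- .mat_row("cardiac_vapor", "RFA")
  a <- model$cap_const + model$Vc * rl$rho * rl$cp
  b <- model$cap_const + model$Vc * cst$L_vap / (cst$T_band_hi - cst$T_band_lo)
  cc <- model$cap_const + model$Vc * rv$rho * rv$cp
  H99 <- a * (cst$T_band_lo - 37)
  H100 <- H99 + b * (cst$T_band_hi - cst$T_band_lo)
  T <- 37 + H / a
  mid <- H > H99 & H <= H100
  T[mid] <- (cst$T_band_lo + (H - H99) / b)[mid]
  hi <- H > H100
  T[hi] <- (cst$T_band_hi + (H - H100) / cc)[hi]
  T
}

#' Advance the thermal state by one implicit step
#'
#' One backward-Euler step of the bioheat equation with the given Joule
#' source. The phase-change band is honoured by an energy-consistent
#' enthalpy correction: the energy each node gains in the linearised step is
#' remapped through the exact nodal enthalpy curve, so latent heat is
#' conserved even when a node crosses the 99-100 degC band within one step.
#' Updates the per-node running maximum temperature and the Arrhenius damage
#' accumulator.
#'
#' @param state a [thermal_state()].
#' @param source a [joule_source()] (or `NULL` for no heating).
#' @param dt time step, s (positive).
#' @return the advanced `thermal_state`.
#' @export
step_temperature <- function(state, source, dt) {
  if (dt <= 0) stop("dt must be positive")
  model <- state$model
  mesh <- model$mesh
  T_old <- state$T
  q <- if (is.null(source)) numeric(nrow(mesh$elems)) else source$q

  capd <- .cap_diag(model, T_old)
  # a handful of nodes with a stale capacity segment is tolerated: the
  # enthalpy correction keeps the step energy-consistent regardless, and the
  # conductivity lag threshold forces a rebuild as the hot region evolves
  rebuild <- is.null(model$Tk_ref) || !identical(dt, model$dt_last) ||
    max(abs(T_old - model$Tk_ref)) > model$k_lag ||
    sum(abs(capd - model$cap_ref) / model$cap_ref > 0.5) > 3

  # explicit advection sub-steps (blood region only); the discrete transport
  # operator is not monotone, so the global floor (inflow/initial 37 degC,
  # which no advective process can undercut) is enforced after each sub-step
  T_star <- T_old
  if (!is.null(model$C_adv)) {
    n_sub <- max(1L, ceiling(dt / model$dt_cfl))
    dts <- dt / n_sub
    floor_T <- min(37, min(T_old))
    for (ss in seq_len(n_sub)) {
      T_star <- T_star - dts * as.numeric(model$C_adv %*% T_star) / capd
      T_star <- pmax(T_star, floor_T)
      T_star[model$fixed] <- model$fixed_vals
    }
  }

  if (rebuild || is.null(model$fact)) {
    K <- .assemble_from_parts(model$parts, .k_map(model, T_old))
    A <- K + Matrix::Diagonal(x = capd / dt)
    Aff <- Matrix::forceSymmetric(A[model$free, model$free])
    model$Afd <- A[model$free, model$fixed, drop = FALSE]
    if (is.null(model$fact)) model$fact <- Matrix::Cholesky(Aff, LDL = FALSE)
    else model$fact <- Matrix::update(model$fact, Aff)
    model$Tk_ref <- T_old
    model$dt_last <- dt
    model$cap_ref <- capd
  }
  load <- .nodal_volumes_weighted(mesh, q)
  rhs <- (model$cap_ref / dt) * T_star + load
  b <- rhs[model$free] - as.numeric(model$Afd %*% model$fixed_vals)
  T_new <- numeric(length(T_old))
  T_new[model$fixed] <- model$fixed_vals
  T_new[model$free] <- as.numeric(Matrix::solve(model$fact, b))

  if (!model$const_props && any(model$Vc > 0)) {
    # enthalpy correction on free nodes that moved across a capacity segment
    H_new <- .node_enthalpy(model, T_star) + model$cap_ref * (T_new - T_star)
    T_corr <- .node_enthalpy_inverse(model, H_new)
    T_corr[model$fixed] <- model$fixed_vals
    T_new <- T_corr
  }

  state$T <- T_new
  state$T_max <- pmax(state$T_max, T_new)
  state$omega <- state$omega + dt * (arrhenius_rate(T_old) + arrhenius_rate(T_new)) / 2
  state$t <- state$t + dt
  state
}

# nodal load vector from an element density (int phi_i q)
.nodal_volumes_weighted <- function(mesh, q_elem) {
  el <- mesh$elems
  as.numeric(Matrix::sparseMatrix(i = as.vector(el), j = rep(1L, 4 * nrow(el)),
                                  x = rep(mesh$vol / 4 * q_elem, 4),
                                  dims = c(mesh$n_nodes %||% max(el), 1)))
}

# total enthalpy content of the domain relative to 37 degC (energy audit)
.total_enthalpy <- function(model, T_nodes) {
  H <- sum(model$cap_const * (T_nodes - 37))
  if (any(model$Vc > 0)) {
    H <- H - sum(model$cap_const * 0)    # cap_const handled above
    if (model$const_props) {
      rl <- .mat_row("cardiac", "RFA")
      H <- H + sum(model$Vc * rl$rho * rl$cp * (T_nodes - 37))
    } else {
      H <- H + sum(model$Vc * material_enthalpy(T_nodes, "cardiac"))
    }
  }
  H
}
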