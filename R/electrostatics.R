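# Quasi-static electric solves: generalized Laplace problem with
# modality-specific conductivity, including the nonlinear field-dependent
# electroporation solve.

#' RMS-equivalent applied voltage
#'
#' The quasi-static solver applies a DC voltage equal to the RMS value of the
#' physical waveform: `V_P / sqrt(2)` for the 500 kHz sinusoid used in RFA,
#' and `V_P` itself for the biphasic square bursts used in PFA.
#'
#' @param waveform_kind `"sinusoid"` or `"biphasic"`.
#' @param V_P waveform amplitude, V (non-negative).
#' @return RMS voltage, V.
#' @export
rms_equivalent_voltage <- function(waveform_kind = c("sinusoid", "biphasic"), V_P) {
  waveform_kind <- match.arg(waveform_kind)
  stopifnot(all(V_P >= 0))
  switch(waveform_kind, sinusoid = V_P / sqrt(2), biphasic = V_P)
}

# Conductivity map (S/m per element) for a given modality and nodal
# temperature field. For PFA an element field magnitude (V/m) enters the
# electroporation sigmoid for biological materials.
sigma_map <- function(mesh, modality = "RFA", T_nodes = 37, E_elem = NULL) {
  Tn <- if (length(T_nodes) == 1) rep(T_nodes, mesh$n_nodes) else T_nodes
  Te <- rowMeans(matrix(Tn[mesh$elems], ncol = 4))
  reg <- mesh$region
  sig <- numeric(length(reg))
  matmap <- c(blood = "blood", cardiac = "cardiac", skeletal = "skeletal",
              electrode = "electrode", electrode_gnd = "electrode",
              insulation = "insulation", sensor = "sensor")
  for (rg in unique(reg)) {
    mat <- matmap[[rg]]
    if (modality == "RFA" || !(mat %in% c("blood", "cardiac", "skeletal"))) {
      if (modality == "PFA" && mat == "sensor") mat <- "insulation"
      sig[reg == rg] <- sigma_rfa(Te[reg == rg], mat) *
        (if (modality == "PFA") .pfa_over_rfa_sigma0(mat) else 1)
    } else {
      E_vcm <- if (is.null(E_elem)) 0 else E_elem[reg == rg] / 100
      sig[reg == rg] <- sigma_pfa(E_vcm, Te[reg == rg], mat)
    }
  }
  sig
}

# ratio of PFA to RFA baseline conductivity for non-biological materials (1)
.pfa_over_rfa_sigma0 <- function(mat) 1

#' Solve the quasi-static potential problem
#'
#' Discrete solution of `div(sigma grad Phi) = 0` with Dirichlet conditions on
#' the active electrode(s) (`V`) and ground (`0`). The electric field is
#' computed per element as `|grad Phi|`.
#'
#' @param mesh an `ablation_mesh` (or fixture mesh with node sets).
#' @param sigma per-element conductivity, S/m (strictly positive); default is
#'   the modality conductivity map at 37 degC.
#' @param V applied electrode voltage (RMS-equivalent), V.
#' @param active_nodes,ground_nodes Dirichlet node sets; default from the mesh.
#' @param dirichlet_values optional named list overriding the fixed potential
#'   values (`active`, `ground`) or a full vector of values for
#'   `c(active_nodes, ground_nodes)`.
#' @param cache optional environment to reuse the symbolic factorization
#'   across repeated solves on the same mesh.
#' @return an object of class `field_solution`: nodal potential `phi` (V),
#'   element field magnitude `E_elem` (V/m), element conductivity `sigma`,
#'   delivered current `I` (A), impedance `Z` (ohm) and the current-balance
#'   error of active vs ground electrodes.
#' @export
solve_potential <- function(mesh, sigma = NULL, V = 1,
                            active_nodes = mesh$active_nodes,
                            ground_nodes = mesh$ground_nodes,
                            dirichlet_values = NULL, cache = NULL, parts = NULL) {
  if (is.null(sigma)) sigma <- sigma_map(mesh, "RFA", 37)
  if (any(sigma <= 0)) stop("sigma map must be strictly positive")
  if (!length(active_nodes) || !length(ground_nodes))
    stop("need at least one active and one ground electrode boundary (singular system otherwise)")
  if (is.null(parts) && !is.null(cache)) {
    if (is.null(cache$parts)) cache$parts <- .stiffness_parts(mesh)
    parts <- cache$parts
  }
  if (is.null(parts)) parts <- .stiffness_parts(mesh)
  K <- .assemble_from_parts(parts, sigma)
  fixed <- c(active_nodes, ground_nodes)
  vals <- if (is.null(dirichlet_values))
    c(rep(V, length(active_nodes)), rep(0, length(ground_nodes)))
  else if (is.list(dirichlet_values))
    c(rep(dirichlet_values$active, length(active_nodes)),
      rep(dirichlet_values$ground, length(ground_nodes)))
  else dirichlet_values
  phi <- .dirichlet_solve(K, numeric(nrow(K)), fixed, vals, cache = cache)
  gr <- .element_gradient(mesh, phi)
  E_elem <- sqrt(rowSums(gr^2))
  r <- as.numeric(K %*% phi)
  I_active <- sum(r[active_nodes]); I_ground <- sum(r[ground_nodes])
  bal <- abs(I_active + I_ground) / max(abs(I_active), .Machine$double.eps)
  structure(list(phi = phi, E_elem = E_elem, E_vec = -gr, sigma = sigma,
                 V = V, I = I_active, Z = if (I_active != 0) V / I_active else Inf,
                 current_balance = bal, active_nodes = active_nodes,
                 ground_nodes = ground_nodes),
            class = "field_solution")
}

#' Nonlinear pulsed-field-ablation field solve
#'
#' Fixed point of the coupled system: the conductivity of biological tissue
#' rises with the local field magnitude (Gompertz electroporation sigmoid) and
#' with temperature, while the field redistributes with the conductivity.
#' Solved by damped successive substitution (Picard) until the relative L2
#' change of the element field magnitude falls below `tol`.
#'
#' @param mesh an `ablation_mesh`.
#' @param T_field nodal temperature, degC (scalar for a uniform field).
#' @param V_P burst amplitude, V (the DC-equivalent applied voltage).
#' @param relax damping factor on the conductivity update.
#' @param tol convergence threshold on the relative L2 change of `|E|`.
#' @param max_iter maximum Picard iterations.
#' @return a `field_solution` with elements `iterations`, `converged` and
#'   `residual_history`.
#' @export
solve_nonlinear_pfa_field <- function(mesh, T_field = 37, V_P,
                                      relax = 0.7, tol = 1e-3, max_iter = 50) {
  stopifnot(V_P >= 0)
  cache <- new.env(parent = emptyenv())
  sig <- sigma_map(mesh, "PFA", T_field, E_elem = NULL)
  hist <- numeric(0)
  E_old <- NULL; fs <- NULL
  for (it in seq_len(max_iter)) {
    fs <- solve_potential(mesh, sigma = sig, V = V_P, cache = cache)
    if (V_P == 0) { fs$iterations <- it; fs$converged <- TRUE
                    fs$residual_history <- 0; return(fs) }
    if (!is.null(E_old)) {
      res <- sqrt(sum(mesh$vol * (fs$E_elem - E_old)^2) /
                    max(sum(mesh$vol * E_old^2), .Machine$double.eps))
      hist <- c(hist, res)
      if (res < tol) break
    }
    E_old <- fs$E_elem
    sig_new <- sigma_map(mesh, "PFA", T_field, E_elem = fs$E_elem)
    sig <- relax * sig_new + (1 - relax) * sig
  }
  fs$iterations <- it
  fs$converged <- length(hist) > 0 && hist[length(hist)] < tol
  fs$residual_history <- hist
  if (!fs$converged)
    warning("PFA field solve did not reach tol ", tol, " after ", it,
            " iterations; residual history: ",
            paste(signif(hist, 3), collapse = ", "))
  fs
}

#' @export
print.field_solution <- function(x, ...) {
  cat("Quasi-static field solution\n")
  cat(sprintf("  V = %.6g V, I = %.6g A, Z = %.6g ohm\n", x$V, x$I, x$Z))
  cat(sprintf("  current balance error: %.3g\n", x$current_balance))
  if (!is.null(x$iterations))
    cat(sprintf("  nonlinear iterations: %d (converged: %s)\n",
                x$iterations, x$converged))
  invisible(x)
}
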