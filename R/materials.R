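#' @importFrom Matrix sparseMatrix Diagonal Cholesky solve t crossprod
#' @importFrom stats setNames approx
NULL

# Constitutive-law constants shared by both modalities.
.ablatr_const <- list(
  alpha_T    = 0.015,     # conductivity temperature coefficient, 1/degC
  dk         = 0.0012,    # thermal conductivity slope, W/(m K degC)
  Tcap_k     = 100,       # k constant above this temperature, degC
  T_desic_lo = 100,       # desiccation band, degC
  T_desic_hi = 105,
  desic_floor = 1e-4,     # post-desiccation conductivity factor
  T_band_lo  = 99,        # enthalpy (vaporization) band, degC
  T_band_hi  = 100,
  L_vap      = 2.162e9,   # latent heat of tissue water, J/m^3
  d_sigma    = 0.1,       # electroporation conductivity increment, S/m
  b_span     = 0.01,      # Gompertz transition span, cm/V
  E_th_sigma = 500,       # conductivity-rise threshold, V/cm
  E_th_lesion = 1000,     # irreversible electroporation lesion threshold, V/cm
  arr_A      = 2.94e39,   # Arrhenius pre-exponential factor, 1/s
  arr_dE     = 2.596e5,   # Arrhenius activation energy, J/mol
  gas_R      = 8.3143     # gas constant, J/(mol K)
)

.ablatr_materials <- local({
  # sigma0 S/m, k0 W/(m K), rho kg/m^3, cp J/(kg K); per modality where they differ
  m <- data.frame(
    material  = c("electrode", "insulation", "skeletal", "cardiac", "cardiac_vapor",
                  "blood", "sensor"),
    biological = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    sigma0_rfa = c(4.6e6, 1e-5, 0.446, 0.281, NA, 0.748, 1e-5),
    sigma0_pfa = c(4.6e6, 1e-5, 0.373, 0.228, NA, 0.706, NA),
    k0        = c(71, 0.026, 0.49, 0.56, 0.56, 0.52, 0.038),
    rho       = c(21500, 70, 1090, 1081, 370, 1050, 32),
    cp        = c(132, 1045, 3421, 3686, 2155.92, 3617, 835),
    stringsAsFactors = FALSE
  )
  rownames(m) <- m$material
  m
})

#' Material property table
#'
#' Baseline electrical and thermal properties of every material in the model,
#' at 500 kHz for radiofrequency ablation (RFA) and 150 kHz for pulsed field
#' ablation (PFA). The temperature sensor only exists in RFA models; the vapor
#' phase only exists for cardiac tissue.
#'
#' @param modality `"RFA"` or `"PFA"`.
#' @return A data frame with columns `material`, `sigma0` (S/m), `k0`
#'   (W/(m K)), `rho` (kg/m^3), `cp` (J/(kg K)) and `biological`.
#' @export
material_table <- function(modality = c("RFA", "PFA")) {
  modality <- match.arg(toupper(modality), c("RFA", "PFA"))
  m <- .ablatr_materials
  sig <- if (modality == "RFA") m$sigma0_rfa else m$sigma0_pfa
  out <- data.frame(material = m$material, sigma0 = sig, k0 = m$k0,
                    rho = m$rho, cp = m$cp, biological = m$biological,
                    stringsAsFactors = FALSE)
  if (modality == "PFA") out <- out[out$material != "sensor", ]
  rownames(out) <- out$material
  out
}

.mat_row <- function(material, modality) {
  tab <- material_table(modality)
  if (!all(material %in% tab$material))
    stop("unknown material: ", paste(setdiff(material, tab$material), collapse = ", "))
  tab[material, , drop = FALSE]
}

# temperature factor exp(alpha (T - 37)) with the cardiac desiccation collapse:
# linear decrease from f(100) to 1e-4 f(100) across 100..105 degC, constant after.
.sigma_T_factor <- function(T, desiccates) {
  cst <- .ablatr_const
  f <- exp(cst$alpha_T * (T - 37))
  if (desiccates) {
    f100 <- exp(cst$alpha_T * (cst$T_desic_lo - 37))
    mid <- T > cst$T_desic_lo & T <= cst$T_desic_hi
    hi  <- T > cst$T_desic_hi
    frac <- (T[mid] - cst$T_desic_lo) / (cst$T_desic_hi - cst$T_desic_lo)
    f[mid] <- f100 * (1 - (1 - cst$desic_floor) * frac)
    f[hi]  <- f100 * cst$desic_floor
  }
  f
}

#' Electrical conductivity during radiofrequency ablation
#'
#' Conductivity of a material at 500 kHz as a function of temperature.
#' Biological materials grow exponentially at +1.5 %/degC; cardiac tissue
#' additionally desiccates above 100 degC, its conductivity dropping linearly
#' by four orders of magnitude across 100-105 degC and staying at that floor
#' above. Catheter materials are temperature-independent.
#'
#' @param T temperature, degC (vectorised).
#' @param material one of `"cardiac"`, `"skeletal"`, `"blood"`, `"electrode"`,
#'   `"insulation"`, `"sensor"`.
#' @return conductivity, S/m.
#' @export
sigma_rfa <- function(T, material = "cardiac") {
  stopifnot(all(T >= 0))
  row <- .mat_row(material, "RFA")
  if (!row$biological) return(rep(row$sigma0, length(T)))
  row$sigma0 * .sigma_T_factor(T, desiccates = identical(material, "cardiac"))
}

#' Electrical conductivity during pulsed field ablation
#'
#' Conductivity at 150 kHz as a function of local electric field magnitude and
#' temperature. The field dependence is a Gompertz sigmoid modelling the
#' conductivity rise caused by electroporation,
#' `sigma(E) = sigma0 + 0.1 * exp(-exp(-0.01 (|E| - 500)))` (E in V/cm),
#' multiplied by the same temperature factor used for RFA (exponential growth,
#' with the desiccation collapse above 100 degC for cardiac tissue only).
#'
#' @param E_vcm electric field magnitude, V/cm (vectorised).
#' @param T temperature, degC (scalar or same length as `E_vcm`).
#' @param material material name (see [sigma_rfa()]).
#' @return conductivity, S/m.
#' @export
sigma_pfa <- function(E_vcm, T = 37, material = "cardiac") {
  stopifnot(all(E_vcm >= 0))
  cst <- .ablatr_const
  row <- .mat_row(material, "PFA")
  if (!row$biological) return(rep(row$sigma0, length(E_vcm)))
  sE <- row$sigma0 + cst$d_sigma * exp(-exp(-cst$b_span * (E_vcm - cst$E_th_sigma)))
  sE * .sigma_T_factor(T, desiccates = identical(material, "cardiac"))
}

#' Thermal conductivity
#'
#' Biological materials: `k0 + 0.0012 (T - 37)` W/(m K) up to 100 degC,
#' constant above (continuous at 100 degC). Catheter materials are constant.
#'
#' @inheritParams sigma_rfa
#' @return thermal conductivity, W/(m K).
#' @export
thermal_conductivity <- function(T, material = "cardiac") {
  stopifnot(all(T >= 0))
  cst <- .ablatr_const
  row <- .mat_row(material, "RFA")
  if (!row$biological) return(rep(row$k0, length(T)))
  row$k0 + cst$dk * (pmin(T, cst$Tcap_k) - 37)
}

#' Volumetric enthalpy of a material
#'
#' Enthalpy relative to 37 degC, J/m^3. For cardiac tissue the enthalpy
#' carries the latent heat of water vaporization (2.162e9 J/m^3) across the
#' 99-100 degC band and switches to vapor-phase heat capacity above; all other
#' materials are single-phase with constant volumetric heat capacity.
#'
#' @inheritParams sigma_rfa
#' @return enthalpy density, J/m^3.
#' @export
material_enthalpy <- function(T, material = "cardiac") {
  cst <- .ablatr_const
  if (identical(material, "cardiac")) {
    rl <- .mat_row("cardiac", "RFA"); rv <- .mat_row("cardiac_vapor", "RFA")
    cl <- rl$rho * rl$cp; cv <- rv$rho * rv$cp
    lo <- cst$T_band_lo; hi <- cst$T_band_hi
    h <- cl * (pmin(T, lo) - 37)
    mid <- T > lo
    h[mid] <- h[mid] + (pmin(T[mid], hi) - lo) / (hi - lo) * cst$L_vap
    vap <- T > hi
    h[vap] <- h[vap] + cv * (T[vap] - hi)
    h
  } else {
    row <- .mat_row(material, "RFA")
    row$rho * row$cp * (T - 37)
  }
}

#' Effective volumetric heat capacity (enthalpy method)
#'
#' Piecewise derivative of the enthalpy with respect to temperature: for
#' cardiac tissue `rho_l c_l` below 99 degC, the latent heat per degC
#' (2.162e9 J/(m^3 K)) inside the 99-100 degC vaporization band and
#' `rho_v c_v` above 100 degC. All other materials have constant `rho cp`.
#'
#' @inheritParams sigma_rfa
#' @return effective volumetric heat capacity, J/(m^3 K).
#' @export
effective_heat_capacity <- function(T, material = "cardiac") {
  stopifnot(all(T >= 0))
  cst <- .ablatr_const
  if (identical(material, "cardiac")) {
    rl <- .mat_row("cardiac", "RFA"); rv <- .mat_row("cardiac_vapor", "RFA")
    out <- rep(rl$rho * rl$cp, length(T))
    out[T > cst$T_band_lo & T <= cst$T_band_hi] <-
      cst$L_vap / (cst$T_band_hi - cst$T_band_lo)
    out[T > cst$T_band_hi] <- rv$rho * rv$cp
    out
  } else {
    row <- .mat_row(material, "RFA")
    rep(row$rho * row$cp, length(T))
  }
}

#' Constitutive constants
#'
#' The fixed constants of the constitutive laws: temperature coefficient of
#' conductivity, thermal-conductivity slope, electroporation sigmoid
#' parameters, latent heat, lesion thresholds and Arrhenius kinetics.
#'
#' @return a named list.
#' @export
constitutive_params <- function() .ablatr_const
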