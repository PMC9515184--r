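# Scenario configuration and parametric geometry.
#
# Coordinates: z = 0 at the undeformed endocardial (blood-cardiac) plane,
# z positive into the blood pool, blood flow along +x. All lengths in metres
# internally; user-facing dimensions in the config are given in the units
# stated by each argument.

.MM <- 1e-3

#' Scenario configuration
#'
#' Assembles and validates the full parameter set of one ablation scenario:
#' treatment modality, catheter configuration and orientation, blood inlet
#' velocity, applied voltage (PFA), treatment duration and mesh resolution.
#'
#' @param modality `"RFA"` (temperature-controlled radiofrequency) or `"PFA"`
#'   (pulsed field / irreversible electroporation).
#' @param catheter_config `"monopolar"` (tip electrode vs dispersive bottom
#'   patch) or `"bipolar"` (ring array with alternating polarity).
#' @param inlet_velocity blood inlet speed, m/s, in \[0, 0.2\].
#' @param alpha_deg catheter tilt from the surface normal (monopolar), degrees
#'   in \[0, 60\].
#' @param beta_deg angle between catheter (projection) and blood-flow
#'   direction, degrees in \[0, 60\].
#' @param applied_voltage PFA burst amplitude, V. Ignored for RFA, whose
#'   voltage comes from the PI controller. Defaults to the calibrated
#'   depth-matched values: 3100 V monopolar, 1400 V bipolar.
#' @param duration treatment time, s. Defaults: 30 s RFA, 20 s PFA.
#' @param mesh_resolution one of `"coarse"`, `"medium"`, `"paper"`, `"fine"`.
#' @param half_domain logical; simulate only y >= 0 with a symmetry plane at
#'   y = 0. Only allowed for mirror-symmetric scenarios (beta = 0).
#' @param random_seed integer seed recorded with the scenario (all solvers are
#'   deterministic).
#' @param tip_length_mm exposed tip-electrode length (monopolar), mm.
#' @param viscosity blood dynamic viscosity, Pa s.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(modality = c("RFA", "PFA"),
                            catheter_config = c("monopolar", "bipolar"),
                            inlet_velocity = 0.06,
                            alpha_deg = 0, beta_deg = 0,
                            applied_voltage = NULL,
                            duration = NULL,
                            mesh_resolution = "coarse",
                            half_domain = FALSE,
                            random_seed = 1L,
                            tip_length_mm = 4,
                            viscosity = 0.0021) {
  modality <- match.arg(toupper(modality), c("RFA", "PFA"))
  catheter_config <- match.arg(catheter_config)
  if (inlet_velocity < 0 || inlet_velocity > 0.2)
    stop("inlet_velocity must lie in [0, 0.2] m/s")
  if (alpha_deg < 0 || alpha_deg > 60) stop("alpha_deg must lie in [0, 60] degrees")
  if (beta_deg < 0 || beta_deg > 60) stop("beta_deg must lie in [0, 60] degrees")
  if (!mesh_resolution %in% names(.mesh_presets()))
    stop("unknown mesh_resolution: ", mesh_resolution)
  if (is.null(duration)) duration <- if (modality == "RFA") 30 else 20
  if (duration <= 0) stop("duration must be positive")
  if (is.null(applied_voltage))
    applied_voltage <- if (catheter_config == "monopolar") 3100 else 1400
  if (half_domain && beta_deg != 0)
    stop("half_domain requires a mirror-symmetric scenario (beta_deg = 0)")
  structure(list(
    modality = modality, catheter_config = catheter_config,
    inlet_velocity = inlet_velocity,
    alpha_deg = alpha_deg, beta_deg = beta_deg,
    applied_voltage = applied_voltage, duration = duration,
    mesh_resolution = mesh_resolution, half_domain = half_domain,
    random_seed = as.integer(random_seed),
    tip_length_mm = tip_length_mm, viscosity = viscosity
  ), class = "scenario_config")
}

#' Read / write a scenario configuration as YAML
#'
#' @param path file path.
#' @param config a `scenario_config`.
#' @return `read_scenario` returns a `scenario_config`.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scenario_config, vals)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the simulation-domain geometry for a scenario
#'
#' Constructs the parametric three-layer slab (blood 40 mm / myocardium 20 mm
#' / skeletal muscle 60 mm over an 80 x 80 mm footprint) with a 7 Fr (2.33 mm)
#' catheter. The monopolar catheter carries a 4 mm tip electrode inserted
#' 1.25 mm into the myocardium and tilted by `alpha` about the contact point
#' (tilt direction rotated by `beta` from the flow axis); the dispersive
#' ground electrode is the slab bottom. The bipolar catheter lies horizontally
#' on the surface (0.5 mm insertion) with four 4 mm ring electrodes separated
#' by 2 mm gaps, energized with alternating polarity, its axis rotated by
#' `beta` from the flow direction. RFA geometries embed a
#' 0.3 x 0.3 x 0.75 mm temperature-sensor box inside the electrode.
#'
#' @param config a [scenario_config()].
#' @return an object of class `ablation_geometry`.
#' @export
build_geometry <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  slab <- list(X = 80 * .MM, Y = 80 * .MM,
               z_blood = 40 * .MM, z_cardiac = 20 * .MM, z_skeletal = 60 * .MM)
  r <- 2.33 / 2 * .MM
  alpha <- config$alpha_deg * pi / 180
  beta  <- config$beta_deg * pi / 180
  mono <- config$catheter_config == "monopolar"
  if (mono) {
    D_E <- 1.25 * .MM
    tip_len <- config$tip_length_mm * .MM
    len <- 20 * .MM                       # inserted catheter length modelled
    axis <- c(sin(alpha) * cos(beta), sin(alpha) * sin(beta), cos(alpha))
    base <- c(0, 0, r - D_E)              # centre of hemispherical tip cap
    s_tip <- tip_len - r                  # electrode extends from apex to s_tip
    # sensor: box centred on the axis at the distal end of the tip (real
    # ablation catheters embed the thermistor at the tip apex), starting
    # 0.3 mm behind the apex, 0.75 mm long, 0.3 mm square cross-section
    sensor <- list(s_lo = -r + 0.3 * .MM, s_hi = -r + 1.05 * .MM,
                   half_w = 0.15 * .MM)
    electrodes <- list(list(s_lo = -2 * r, s_hi = s_tip, polarity = 1))
    cath <- list(type = "monopolar", radius = r, axis = axis, base = base,
                 s_min = 0, s_max = len, cap_lo = TRUE, cap_hi = FALSE,
                 D_E = D_E, tip_len = tip_len, electrodes = electrodes,
                 sensor = if (config$modality == "RFA") sensor else NULL)
  } else {
    D_E <- 0.5 * .MM
    axis <- c(cos(beta), sin(beta), 0)
    base <- c(0, 0, r - D_E)
    ring_len <- 4 * .MM; gap <- 2 * .MM; n_ring <- 4
    span <- n_ring * ring_len + (n_ring - 1) * gap
    s0 <- -span / 2
    electrodes <- lapply(seq_len(n_ring), function(i) {
      lo <- s0 + (i - 1) * (ring_len + gap)
      list(s_lo = lo, s_hi = lo + ring_len, polarity = if (i %% 2 == 1) 1 else 0)
    })
    half_len <- span / 2 + 4 * .MM
    e2 <- electrodes[[2]]                 # sensor at second ring of the array
    mid <- (e2$s_lo + e2$s_hi) / 2
    sensor <- list(s_lo = mid - 0.375 * .MM, s_hi = mid + 0.375 * .MM,
                   half_w = 0.15 * .MM)
    cath <- list(type = "bipolar", radius = r, axis = axis, base = base,
                 s_min = -half_len, s_max = half_len, cap_lo = TRUE, cap_hi = TRUE,
                 D_E = D_E, electrodes = electrodes,
                 sensor = if (config$modality == "RFA") sensor else NULL)
  }
  structure(list(config = config, slab = slab, catheter = cath,
                 half_domain = config$half_domain), class = "ablation_geometry")
}

# Orthonormal frame of the catheter: axis a, transverse e1 (in the tilt plane),
# e2 = a x e1.
.cath_frame <- function(cath) {
  a <- cath$axis
  up <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  list(a = a, e1 = e1, e2 = e2)
}

# Region classification of points (n x 3 matrix, metres).
# Returns a character vector: blood/cardiac/skeletal/electrode/electrode_gnd/
# insulation/sensor.
classify_points <- function(geometry, pts) {
  cath <- geometry$catheter
  a <- cath$axis; b <- cath$base; r <- cath$radius
  px <- pts[, 1] - b[1]; py <- pts[, 2] - b[2]; pz <- pts[, 3] - b[3]
  s <- px * a[1] + py * a[2] + pz * a[3]
  d2 <- pmax(px^2 + py^2 + pz^2 - s^2, 0)
  inside <- (s >= cath$s_min & s <= cath$s_max & d2 <= r^2)
  if (cath$cap_lo) inside <- inside |
      (s < cath$s_min & (d2 + (s - cath$s_min)^2) <= r^2)
  if (cath$cap_hi) inside <- inside |
      (s > cath$s_max & (d2 + (s - cath$s_max)^2) <= r^2)

  region <- character(nrow(pts))
  z <- pts[, 3]
  region[z > 0] <- "blood"
  region[z <= 0 & z > -geometry$slab$z_cardiac] <- "cardiac"
  region[z <= -geometry$slab$z_cardiac] <- "skeletal"

  idx <- which(inside)
  if (length(idx)) {
    region[idx] <- "insulation"
    si <- s[idx]
    for (el in cath$electrodes) {
      in_el <- si >= el$s_lo & si <= el$s_hi
      region[idx[in_el]] <- if (el$polarity > 0) "electrode" else "electrode_gnd"
    }
    sen <- cath$sensor
    if (!is.null(sen)) {
      fr <- .cath_frame(cath)
      u <- px[idx] * fr$e1[1] + py[idx] * fr$e1[2] + pz[idx] * fr$e1[3]
      v <- px[idx] * fr$e2[1] + py[idx] * fr$e2[2] + pz[idx] * fr$e2[3]
      in_sen <- si >= sen$s_lo & si <= sen$s_hi &
        abs(u) <= sen$half_w & abs(v) <= sen$half_w
      region[idx[in_sen]] <- "sensor"
    }
  }
  region
}

# Analytic volume of the catheter portion below z = 0 for the perpendicular
# monopolar reference (used by the region-volume audit).
.mono_submerged_volume <- function(geometry) {
  cath <- geometry$catheter
  r <- cath$radius; zc <- cath$base[3]   # tip-cap centre height (negative)
  if (zc >= 0) {           # only part of the hemisphere is submerged
    h <- r - zc
    return(pi * h^2 * (3 * r - h) / 3 - 0)
  }
  2 / 3 * pi * r^3 + pi * r^2 * (-zc)
}
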