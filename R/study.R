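# Declarative studies: reference comparisons, blood-velocity sweeps and
# catheter-orientation sweeps, reproducing the comparison tables.

#' Define a parameter-sweep study
#'
#' @param base a [scenario_config()] used for every sweep point.
#' @param parameter name of the swept scenario field (`"inlet_velocity"`,
#'   `"alpha_deg"` or `"beta_deg"`).
#' @param values sweep values (scenario units; velocities in m/s).
#' @param out_dir optional directory; when given, `run_study()` writes
#'   `results.csv` there.
#' @return an object of class `study_config`.
#' @export
study_config <- function(base, parameter, values, out_dir = NULL) {
  stopifnot(inherits(base, "scenario_config"),
            parameter %in% c("inlet_velocity", "alpha_deg", "beta_deg"))
  structure(list(base = base, parameter = parameter, values = values,
                 out_dir = out_dir), class = "study_config")
}

#' Run a study
#'
#' Executes the flow / protocol / lesion pipeline for every sweep point.
#' Individual point failures are recorded (row of NAs) and the study
#' continues. Meshes are re-used across sweep points that share geometry
#' (velocity sweeps).
#'
#' @param study a [study_config()].
#' @param ... passed to [ablate()].
#' @return a data frame with one row per sweep point: lesion metrics, peak
#'   temperatures, mean power and runtime.
#' @export
run_study <- function(study, ...) {
  stopifnot(inherits(study, "study_config"))
  vals <- study$values
  rows <- vector("list", length(vals))
  mesh <- NULL
  reuse_mesh <- study$parameter == "inlet_velocity"
  if (reuse_mesh && length(vals))
    mesh <- generate_mesh(build_geometry(study$base))
  for (i in seq_along(vals)) {
    cfg <- study$base
    cfg[[study$parameter]] <- vals[i]
    cfg <- do.call(scenario_config, unclass(cfg))
    t0 <- Sys.time()
    rows[[i]] <- tryCatch({
      ab <- if (reuse_mesh) ablate(cfg, mesh = mesh, ...) else ablate(cfg, ...)
      s <- summary(ab)
      data.frame(parameter = study$parameter, value = vals[i],
                 modality = cfg$modality,
                 V_mm3 = s$metrics$V_mm3, depth_mm = s$metrics$depth_mm,
                 width_mm = s$metrics$width_mm,
                 width_transversal_mm = s$metrics$width_transversal_mm,
                 sr_up = s$metrics$sr[1], sr_down = s$metrics$sr[2],
                 maxT_blood = s$maxT_blood, maxT_cardiac = s$maxT_cardiac,
                 mean_power_W = s$mean_power,
                 runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }, error = function(e) {
      warning("sweep point ", vals[i], " failed: ", conditionMessage(e))
      data.frame(parameter = study$parameter, value = vals[i],
                 modality = study$base$modality,
                 V_mm3 = NA_real_, depth_mm = NA_real_, width_mm = NA_real_,
                 width_transversal_mm = NA_real_, sr_up = NA_real_,
                 sr_down = NA_real_, maxT_blood = NA_real_,
                 maxT_cardiac = NA_real_, mean_power_W = NA_real_,
                 runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    })
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(0), value = numeric(0))
  if (!is.null(study$out_dir)) {
    dir.create(study$out_dir, showWarnings = FALSE, recursive = TRUE)
    # runtime is wall-clock metadata; excluded so the CSV is bit-reproducible
    utils::write.csv(out[, setdiff(names(out), "runtime_s"), drop = FALSE],
                     file.path(study$out_dir, "results.csv"),
                     row.names = FALSE)
  }
  out
}

#' Calibrate the PFA voltage to a target lesion depth
#'
#' Bisection on the burst amplitude until the 1000 V/cm lesion depth matches
#' `target_depth_mm` within `tol_mm`. The depth is evaluated from the
#' nonlinear field solve at baseline temperature (the pulsed-field lesion is
#' insensitive to the slow thermal drift, which is why a field-only
#' calibration reproduces the full-protocol depth).
#'
#' @param target_depth_mm target depth below the endocardial plane, mm.
#' @param config a PFA [scenario_config()].
#' @param mesh optional pre-built mesh.
#' @param bounds voltage search interval, V.
#' @param tol_mm depth tolerance, mm.
#' @return the calibrated voltage (attribute `depth_mm` carries the achieved
#'   depth).
#' @export
calibrate_pfa_voltage <- function(target_depth_mm, config, mesh = NULL,
                                  bounds = c(50, 8000), tol_mm = 0.05) {
  stopifnot(target_depth_mm > 0, config$modality == "PFA")
  if (is.null(mesh)) mesh <- generate_mesh(build_geometry(config))
  depth_at <- function(V) {
    fs <- solve_nonlinear_pfa_field(mesh, 37, V)
    f <- lesion_field_vcm(mesh, fs$E_elem); f[is.na(f)] <- 0
    lesion_metrics(extract_lesion_region(mesh, f, .ablatr_const$E_th_lesion))$depth_mm
  }
  lo <- bounds[1]; hi <- bounds[2]
  d_lo <- depth_at(lo); d_hi <- depth_at(hi)
  if (d_lo > target_depth_mm || d_hi < target_depth_mm)
    stop("target depth ", target_depth_mm, " mm unreachable in [",
         lo, ", ", hi, "] V (depths ", signif(d_lo, 3), " - ", signif(d_hi, 3), ")")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    d <- depth_at(mid)
    if (abs(d - target_depth_mm) < tol_mm) {
      return(structure(mid, depth_mm = d))
    }
    if (d < target_depth_mm) lo <- mid else hi <- mid
  }
  structure(mid, depth_mm = d)
}
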