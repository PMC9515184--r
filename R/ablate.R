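# Top-level driver: run one ablation scenario end to end and return a
# classed result with lesion metrics.

#' Simulate one ablation treatment
#'
#' Runs the full pipeline for a scenario: geometry and mesh construction,
#' stationary blood-flow solve, the treatment protocol (PI-controlled RFA for
#' 30 s or the 20-burst PFA schedule), lesion extraction (50 degC
#' max-temperature isotherm for RFA, 1000 V/cm maximum field for PFA) and
#' morphometry.
#'
#' @param config a [scenario_config()] (or arguments forwarded to it).
#' @param ... passed to [run_rfa()] / [run_pfa()].
#' @return an object of class `ablation` containing the protocol run
#'   (`$run`), the lesion region (`$lesion`) and its metrics (`$metrics`).
#' @export
ablate <- function(config, ...) {
  if (!inherits(config, "scenario_config")) config <- do.call(scenario_config, config)
  run <- if (config$modality == "RFA") run_rfa(config, ...) else run_pfa(config, ...)
  structure(c(ablation_lesion(run), list(run = run, config = config)),
            class = "ablation")
}

#' Lesion region and metrics of a finished run
#'
#' @param run an `ablation_run`.
#' @return list with `lesion` (a `lesion_region`) and `metrics`
#'   (`lesion_metrics`).
#' @export
ablation_lesion <- function(run) {
  mesh <- run$mesh
  cst <- .ablatr_const
  if (run$modality == "RFA") {
    reg <- extract_lesion_region(mesh, run$T_max, 50)
  } else {
    f <- lesion_field_vcm(mesh, run$E_max_elem)
    f[is.na(f)] <- 0
    reg <- extract_lesion_region(mesh, f, cst$E_th_lesion,
                                 elem_values = run$E_max_elem / 100)
  }
  list(lesion = reg, metrics = lesion_metrics(reg))
}

#' @export
print.ablation <- function(x, ...) {
  cat(sprintf("Ablation simulation: %s, %s catheter\n",
              x$config$modality, x$config$catheter_config))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.ablation <- function(object, ...) {
  x <- object
  tr <- x$run$trace
  out <- list(
    modality = x$config$modality,
    catheter = x$config$catheter_config,
    inlet_velocity = x$config$inlet_velocity,
    metrics = x$metrics,
    maxT_blood = if (x$config$modality == "RFA") max(tr$maxT_blood)
                 else max(tr$peak_blood),
    maxT_cardiac = if (x$config$modality == "RFA") max(tr$maxT_cardiac)
                   else max(tr$peak_cardiac),
    mean_power = mean(tr$P),
    duration = x$run$state$t)
  class(out) <- "summary.ablation"
  out
}

#' @export
print.summary.ablation <- function(x, ...) {
  cat(sprintf("%s ablation, %s catheter, %.0f cm/s blood flow, %.0f s\n",
              x$modality, x$catheter, x$inlet_velocity * 100, x$duration))
  print(x$metrics)
  cat(sprintf("  peak temperatures: blood %.1f degC, cardiac %.1f degC\n",
              x$maxT_blood, x$maxT_cardiac))
  cat(sprintf("  mean delivered power: %.2f W\n", x$mean_power))
  invisible(x)
}

#' Plot an ablation result
#'
#' For RFA: applied voltage and sensor temperature against time. For PFA:
#' per-burst peak and end-of-pulse maximum temperatures. A second panel shows
#' the lesion cross-section in the flow-aligned midplane (criterion field
#' with the lesion threshold contour).
#'
#' @param x an `ablation`.
#' @param which `"trace"`, `"lesion"` or both.
#' @param ... unused.
#' @export
plot.ablation <- function(x, which = c("trace", "lesion"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  tr <- x$run$trace
  if ("trace" %in% which) {
    if (x$config$modality == "RFA") {
      graphics::par(mar = c(4, 4, 2, 4))
      graphics::plot(tr$t, tr$T_sensor, type = "l", xlab = "time (s)",
                     ylab = "sensor temperature (degC)", main = "control trace")
      graphics::abline(h = 55, lty = 3)
      graphics::par(new = TRUE)
      graphics::plot(tr$t, tr$V, type = "l", col = "grey50", axes = FALSE,
                     xlab = "", ylab = "")
      graphics::axis(4); graphics::mtext("voltage (V)", 4, line = 2.5)
    } else {
      graphics::plot(tr$burst, tr$peak_cardiac, type = "b", pch = 20,
                     xlab = "burst", ylab = "max temperature (degC)",
                     ylim = range(c(tr$peak_cardiac, tr$rest_cardiac)),
                     main = "burst heating")
      graphics::lines(tr$burst, tr$rest_cardiac, type = "b", pch = 1, lty = 2)
      graphics::legend("topleft", c("during pulse", "pre next burst"),
                       pch = c(20, 1), lty = c(1, 2), bty = "n")
    }
  }
  if ("lesion" %in% which) {
    mesh <- x$run$mesh
    f <- x$lesion$f; thr <- x$lesion$threshold
    nd <- mesh$nodes
    sel <- which(abs(nd[, 2]) < 1.01e-3 & nd[, 3] < 8e-3 & nd[, 3] > -12e-3 &
                   abs(nd[, 1]) < 12e-3)
    graphics::plot(nd[sel, 1] * 1e3, nd[sel, 3] * 1e3,
                   col = ifelse(f[sel] >= thr, "firebrick", "grey80"), pch = 20,
                   cex = 0.5, xlab = "x (mm)", ylab = "z (mm)",
                   main = "lesion midplane", asp = 1)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
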