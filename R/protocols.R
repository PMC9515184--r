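# Treatment drivers: the temperature-controlled RFA loop with PI voltage
# control, and the PFA burst scheduler, orchestrating the electric and
# thermal solvers.

#' PI controller state
#'
#' Position-form proportional-integral controller for temperature-controlled
#' ablation: the applied voltage is `max(0, K_P e + K_I int e dt)` with
#' `e = setpoint - T_sensor`. The integral is frozen while the output is
#' clamped at zero (anti-windup).
#'
#' @param K_P proportional gain, V/degC.
#' @param K_I integral gain, V/(degC s).
#' @param setpoint target sensor temperature, degC.
#' @param dt sampling interval, s.
#' @return an object of class `pi_controller`.
#' @export
pi_controller <- function(K_P = 4.6, K_I = 5.8, setpoint = 55, dt = 0.02) {
  structure(list(K_P = K_P, K_I = K_I, setpoint = setpoint, dt = dt,
                 integral = 0, V = 0), class = "pi_controller")
}

#' One PI controller update
#'
#' @param ctrl a [pi_controller()].
#' @param T_sensor measured sensor temperature, degC.
#' @param dt sampling interval, s (defaults to the controller's).
#' @return the updated controller; element `V` is the commanded voltage.
#' @export
pi_update <- function(ctrl, T_sensor, dt = ctrl$dt) {
  e <- ctrl$setpoint - T_sensor
  integral_try <- ctrl$integral + e * dt
  V <- ctrl$K_P * e + ctrl$K_I * integral_try
  if (V < 0) {
    # anti-windup: freeze the integral while the output is clamped
    V <- 0
    if (ctrl$K_P * e + ctrl$K_I * ctrl$integral >= 0 || e > 0)
      ctrl$integral <- integral_try
  } else {
    ctrl$integral <- integral_try
  }
  ctrl$V <- V
  ctrl
}

#' Sensor temperature
#'
#' The temperature measured by the catheter-embedded sensor: the maximum
#' nodal temperature inside the 0.3 x 0.3 x 0.75 mm sensor box.
#'
#' @param state a `thermal_state`.
#' @param sensor_nodes node indices of the sensor region (default: from the
#'   mesh).
#' @return temperature, degC.
#' @export
sensor_temperature <- function(state, sensor_nodes = state$model$mesh$sensor_nodes) {
  if (!length(sensor_nodes)) stop("empty sensor region")
  max(state$T[sensor_nodes])
}

#' Run a temperature-controlled RFA treatment
#'
#' Closed-loop radiofrequency ablation: every 20 ms the sensor temperature is
#' read, the PI controller updates the applied RMS voltage, the quasi-static
#' field is re-solved with the temperature-dependent conductivity map
#' (exactly, exploiting linearity in V between conductivity rebuilds), and
#' the bioheat equation is advanced by one control interval.
#'
#' @param config a [scenario_config()] with `modality = "RFA"`.
#' @param mesh,flow optional pre-built mesh and flow field (rebuilt from the
#'   config when missing).
#' @param controller a [pi_controller()].
#' @param sigma_lag conductivity-map rebuild threshold, degC.
#' @param progress print progress every `progress` seconds of simulated time
#'   (NULL for silent).
#' @return an object of class `ablation_run`: the protocol trace (`t`, `V`,
#'   `I`, `P`, `T_sensor`, `maxT_blood`, `maxT_cardiac`), the final
#'   `thermal_state`, per-node maximum temperature, Arrhenius damage and the
#'   mesh/flow used.
#' @export
run_rfa <- function(config, mesh = NULL, flow = NULL,
                    controller = pi_controller(), sigma_lag = 1.5,
                    progress = NULL) {
  stopifnot(inherits(config, "scenario_config"), config$modality == "RFA")
  set.seed(config$random_seed)
  if (is.null(mesh)) mesh <- generate_mesh(build_geometry(config))
  if (is.null(flow)) flow <- solve_stationary_flow(
    mesh, config$inlet_velocity, viscosity = config$viscosity,
    tol = 1e-4, max_iter = 30)
  st <- thermal_state(mesh, flow = flow)
  blood_nodes <- sort(unique(as.vector(mesh$elems[mesh$region == "blood", ])))
  cardiac_nodes <- sort(unique(as.vector(mesh$elems[mesh$region == "cardiac", ])))

  dtc <- controller$dt
  n_steps <- round(config$duration / dtc)
  cache <- new.env(parent = emptyenv())
  phi1 <- NULL; q1 <- NULL; I1 <- 0; T_sigma_ref <- NULL
  trace <- matrix(NA_real_, n_steps, 7,
                  dimnames = list(NULL, c("t", "V", "I", "P", "T_sensor",
                                          "maxT_blood", "maxT_cardiac")))
  ctrl <- controller
  for (k in seq_len(n_steps)) {
    Tsen <- sensor_temperature(st)
    ctrl <- pi_update(ctrl, Tsen, dtc)
    V <- ctrl$V
    if (is.null(T_sigma_ref) || max(abs(st$T - T_sigma_ref)) > sigma_lag) {
      sig <- sigma_map(mesh, "RFA", st$T)
      fs1 <- solve_potential(mesh, sigma = sig, V = 1, cache = cache)
      phi1 <- fs1$phi; I1 <- fs1$I
      q1 <- sig * fs1$E_elem^2
      T_sigma_ref <- st$T
    }
    src <- structure(list(q = V^2 * q1), class = "heat_source")
    st <- step_temperature(st, src, dtc)
    trace[k, ] <- c(st$t, V, V * I1, V^2 * I1,
                    Tsen, max(st$T[blood_nodes]), max(st$T[cardiac_nodes]))
    if (!is.null(progress) && (k %% round(progress / dtc) == 0))
      message(sprintf("t = %.1f s, V = %.1f V, T_sensor = %.1f degC",
                      st$t, V, Tsen))
  }
  trace <- as.data.frame(trace)
  # controller health: sustained oscillation after the settling phase
  late <- trace$t > 10
  if (any(late)) {
    osc <- diff(range(trace$T_sensor[late]))
    if (osc > 5)
      warning("controller instability: sensor oscillation amplitude ",
              signif(osc, 3), " degC after 10 s")
  }
  structure(list(config = config, mesh = mesh, flow = flow, trace = trace,
                 state = st, T_max = st$T_max, omega = st$omega,
                 controller = ctrl, modality = "RFA"),
            class = "ablation_run")
}

#' Run a pulsed-field-ablation treatment
#'
#' Burst protocol: `n_bursts` biphasic bursts (simulated as DC pulses of the
#' RMS-equivalent amplitude) of `burst_s` duration at 1 Hz repetition. Before
#' each burst the nonlinear field problem is re-solved at the current
#' temperature; during the burst the Joule source is on (25 us steps), and
#' between bursts the tissue relaxes with geometrically growing steps.
#'
#' @param config a [scenario_config()] with `modality = "PFA"`.
#' @param mesh,flow optional pre-built mesh and flow field.
#' @param n_bursts number of bursts.
#' @param burst_s burst duration, s.
#' @param period_s burst repetition period, s.
#' @return an `ablation_run`; `trace` has one row per burst with the
#'   during-pulse peak and end-of-pulse temperatures, `E_max_elem` carries
#'   the per-element maximum field magnitude over all bursts (V/m).
#' @export
run_pfa <- function(config, mesh = NULL, flow = NULL,
                    n_bursts = 20, burst_s = 100e-6, period_s = 1) {
  stopifnot(inherits(config, "scenario_config"), config$modality == "PFA")
  set.seed(config$random_seed)
  if (is.null(mesh)) mesh <- generate_mesh(build_geometry(config))
  if (is.null(flow)) flow <- solve_stationary_flow(
    mesh, config$inlet_velocity, viscosity = config$viscosity,
    tol = 1e-4, max_iter = 30)
  st <- thermal_state(mesh, flow = flow)
  blood_nodes <- sort(unique(as.vector(mesh$elems[mesh$region == "blood", ])))
  cardiac_nodes <- sort(unique(as.vector(mesh$elems[mesh$region == "cardiac", ])))
  V_P <- config$applied_voltage

  E_max <- numeric(nrow(mesh$elems))
  rows <- vector("list", n_bursts)
  fs <- NULL
  for (b in seq_len(n_bursts)) {
    fs <- solve_nonlinear_pfa_field(mesh, st$T, V_P)
    if (!is.null(fs$converged) && !fs$converged)
      stop("PFA field solve failed to converge at burst ", b)
    E_max <- pmax(E_max, fs$E_elem)
    src <- joule_source(fs)
    peak_b <- peak_c <- -Inf
    n_on <- 4L
    for (s in seq_len(n_on)) {
      st <- step_temperature(st, src, burst_s / n_on)
      peak_b <- max(peak_b, max(st$T[blood_nodes]))
      peak_c <- max(peak_c, max(st$T[cardiac_nodes]))
    }
    end_b <- max(st$T[blood_nodes]); end_c <- max(st$T[cardiac_nodes])
    # inter-burst relaxation with geometrically growing steps
    t_off <- period_s - burst_s
    dt <- burst_s / n_on
    while (t_off > 1e-12) {
      dt <- min(dt * 2, 50e-3, t_off)
      st <- step_temperature(st, NULL, dt)
      t_off <- t_off - dt
    }
    rows[[b]] <- data.frame(
      burst = b, t = st$t, V = V_P, I = fs$I, P = V_P * fs$I,
      peak_blood = peak_b, peak_cardiac = peak_c,
      end_blood = end_b, end_cardiac = end_c,
      rest_blood = max(st$T[blood_nodes]), rest_cardiac = max(st$T[cardiac_nodes]))
  }
  structure(list(config = config, mesh = mesh, flow = flow,
                 trace = do.call(rbind, rows), state = st, T_max = st$T_max,
                 omega = st$omega, E_max_elem = E_max, field = fs,
                 modality = "PFA"),
            class = "ablation_run")
}

#' @export
print.ablation_run <- function(x, ...) {
  cat(sprintf("%s run (%s catheter, %g cm/s blood flow, %g s)\n",
              x$modality, x$config$catheter_config,
              x$config$inlet_velocity * 100, x$state$t))
  if (x$modality == "RFA") {
    cat(sprintf("  final sensor T: %.1f degC, mean power %.2f W\n",
                utils::tail(x$trace$T_sensor, 1), mean(x$trace$P)))
  } else {
    cat(sprintf("  %d bursts at %g V\n", nrow(x$trace), x$config$applied_voltage))
  }
  cat(sprintf("  max T: blood %.1f, cardiac %.1f degC\n",
              max(x$trace$maxT_blood %||% x$trace$peak_blood),
              max(x$trace$maxT_cardiac %||% x$trace$peak_cardiac)))
  invisible(x)
}
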