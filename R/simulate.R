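#' Integration controls
#'
#' Protocol parameters for the time integration: total number of drive
#' cycles, the steady-state analysis window (in cycles) over which maxima
#' are taken, solver tolerances, and output density. Defaults follow the
#' study protocol: 60 cycles with the window over cycles 35-55 so start-up
#' transients are excluded.
#'
#' @param n_cycles Number of drive cycles to integrate (default 60).
#' @param window Two-element cycle interval for the analysis window,
#'   contained in `[0, n_cycles]` (default `c(35, 55)`).
#' @param rtol Relative tolerance of the adaptive 5(4) Runge-Kutta solver.
#' @param atol_radius Absolute tolerance on radii (m).
#' @param atol_velocity Absolute tolerance on wall velocities (m/s).
#' @param samples_per_cycle Trajectory output density; window maxima are
#'   accumulated on solver-internal steps, not on this grid.
#' @param max_steps Step-count cap before the run is declared failed.
#' @return An object of class `cav_controls`.
#' @export
simulation_controls <- function(n_cycles = 60, window = c(35, 55),
                                rtol = 1e-8, atol_radius = 1e-12,
                                atol_velocity = 1e-6,
                                samples_per_cycle = 200,
                                max_steps = 5e6) {
  stopifnot(n_cycles > 0, length(window) == 2, window[1] >= 0,
            window[2] > window[1], window[2] <= n_cycles,
            rtol > 0, atol_radius > 0, atol_velocity > 0,
            samples_per_cycle >= 2, max_steps > 0)
  structure(list(n_cycles = n_cycles, window = window, rtol = rtol,
                 atol_radius = atol_radius, atol_velocity = atol_velocity,
                 samples_per_cycle = samples_per_cycle, max_steps = max_steps),
            class = "cav_controls")
}

# Shared dispatch into the compiled integrator.
.integrate <- function(scen, drive, controls, save_trajectory = TRUE,
                       rtol = NULL) {
  geo <- cluster_geometry(scen$population)
  med <- scen$medium; gas <- scen$gas
  .km_integrate_cpp(
    R0 = geo$radius, S = geo$coupling_strength,
    rho = med$density, cl = med$sound_speed, sigma = med$surface_tension,
    mu = med$viscosity, G = med$shear_modulus, p0 = med$static_pressure,
    pv = med$vapor_pressure, kappa = gas$polytropic_exponent,
    pa = drive$amplitude, f = drive$frequency,
    n_cycles = controls$n_cycles, win_lo = controls$window[1],
    win_hi = controls$window[2],
    rtol = if (is.null(rtol)) controls$rtol else rtol,
    atol_R = controls$atol_radius, atol_U = controls$atol_velocity,
    samples_per_cycle = as.integer(controls$samples_per_cycle),
    max_steps = controls$max_steps, cpf = .coupling_prefactor,
    save_trajectory = save_trajectory)
}

#' Integrate the coupled bubble-cluster equations
#'
#' Runs the coupled Keller-Miksis system for all size classes from the
#' equilibrium state (`R_i = R0_i`, `Rdot_i = 0`) over `n_cycles` drive
#' cycles with an adaptive Dormand-Prince 5(4) integrator. A violent
#' inertial collapse can drive the step size below the representable
#' minimum; such runs are returned with a `"failed"` status and the failure
#' time instead of raising an error, and the window maxima accumulated up to
#' that point are kept.
#'
#' @param scen A [scenario()].
#' @param drive An [acoustic_drive()].
#' @param controls A [simulation_controls()].
#' @return An object of class `cav_trajectory`: a tibble with columns `t`,
#'   `R_1..R_q` (m) and `U_1..U_q` (m/s), with attributes `status`
#'   (`"completed"` or `"failed"`), `fail_time`, `window_maxima` (per-class
#'   running maxima over the analysis window), `scenario`, `drive`,
#'   `controls`, and solver step counts.
#' @export
#' @examples
#' scen <- scenario("water", single_bubble(5e-6))
#' traj <- run_simulation(scen, acoustic_drive(50e3, 500e3),
#'                        simulation_controls(n_cycles = 10, window = c(5, 9)))
#' summarize_window(traj)
run_simulation <- function(scen, drive, controls = simulation_controls()) {
  stopifnot(inherits(scen, "cav_scenario"), inherits(drive, "cav_drive"),
            inherits(controls, "cav_controls"))
  res <- .integrate(scen, drive, controls, save_trajectory = TRUE)
  q <- length(scen$population$radii)
  traj <- res$trajectory
  out <- tibble::as_tibble(cbind(
    data.frame(t = traj$t),
    stats::setNames(as.data.frame(traj$R), paste0("R_", seq_len(q))),
    stats::setNames(as.data.frame(traj$U), paste0("U_", seq_len(q)))))
  structure(out,
            class = c("cav_trajectory", class(out)),
            status = if (res$status == 0) "completed" else "failed",
            fail_time = res$fail_time,
            window_maxima = list(Rmax = res$Rmax, Rmin = res$Rmin,
                                 Umax = res$Umax,
                                 touched = res$window_touched),
            scenario = scen, drive = drive, controls = controls,
            n_steps = res$n_steps, n_rejected = res$n_rejected)
}

#' Per-class window summary
#'
#' Maxima of the expansion ratio `R/R0`, wall speed `|Rdot|` and adiabatic
#' core temperature over the analysis window, per size class. Maxima come
#' from the solver's internal steps (plus interpolated sub-samples), so
#' brief collapse spikes are captured; the temperature maximum is derived
#' from the minimum radius via the adiabatic law. A trajectory that failed
#' before reaching the window yields an unusable summary; one that failed
#' inside the window yields a partial summary with a caveat note.
#'
#' A plain data frame with columns `t`, `R_1..R_q` (and optionally
#' `U_1..U_q`) can also be summarized — e.g. a synthetic or imported
#' trajectory — by supplying `R0`, `gas`, `controls` and `frequency`
#' explicitly; maxima are then taken from the table rows inside the window.
#'
#' @param traj A [run_simulation()] result, or a plain trajectory table.
#' @param controls,gas,R0,frequency Overrides for plain tables; taken from
#'   the trajectory attributes otherwise.
#' @return A tibble of class `cav_summary` with columns `radius`,
#'   `max_expansion_ratio`, `max_wall_speed`, `min_radius`,
#'   `max_temperature`, and attributes `usable`, `partial`, `status`.
#' @export
summarize_window <- function(traj, controls = NULL, gas = NULL, R0 = NULL,
                             frequency = NULL) {
  scen <- attr(traj, "scenario")
  controls <- controls %||% attr(traj, "controls")
  drive <- attr(traj, "drive")
  gas <- gas %||% scen$gas
  R0 <- R0 %||% scen$population$radii
  frequency <- frequency %||% drive$frequency
  stopifnot(!is.null(controls), !is.null(gas), !is.null(R0),
            !is.null(frequency))
  wm <- attr(traj, "window_maxima")
  status <- attr(traj, "status") %||% "completed"
  win_t <- controls$window / frequency
  if (is.null(wm)) {
    # plain table: maxima from rows strictly inside the window
    q <- length(R0)
    keep <- traj$t >= win_t[1] & traj$t <= win_t[2]
    usable <- any(keep)
    Rw <- as.matrix(traj[keep, paste0("R_", seq_len(q)), drop = FALSE])
    ucols <- paste0("U_", seq_len(q))
    Uw <- if (all(ucols %in% names(traj)))
      as.matrix(traj[keep, ucols, drop = FALSE])
    else matrix(0, sum(keep), q)
    wm <- list(Rmax = unname(apply(Rw, 2, max)),
               Rmin = unname(apply(Rw, 2, min)),
               Umax = unname(apply(abs(Uw), 2, max)), touched = usable)
  }
  partial <- status == "failed" && isTRUE(wm$touched) &&
    isTRUE(attr(traj, "fail_time") < win_t[2])
  usable <- isTRUE(wm$touched)
  out <- tibble::tibble(
    radius = R0,
    max_expansion_ratio = wm$Rmax / R0,
    max_wall_speed = wm$Umax,
    min_radius = wm$Rmin,
    max_temperature = bubble_temperature(wm$Rmin, R0, gas))
  structure(out, class = c("cav_summary", class(out)),
            usable = usable, partial = partial, status = status)
}

#' Frequency response of the cluster
#'
#' At fixed drive amplitude, sweeps the frequency grid and reports for each
#' frequency the maximum expansion ratio over all size classes together
#' with the class that attains it. Low frequencies are dominated by the
#' largest bubbles; as frequency rises, progressively smaller classes take
#' over.
#'
#' @param scen A [scenario()].
#' @param amplitude Drive amplitude (Pa).
#' @param frequencies Frequency grid (Hz).
#' @param controls A [simulation_controls()].
#' @return A tibble with columns `frequency`, `max_expansion_ratio`,
#'   `argmax_radius` (m), `status`.
#' @export
frequency_response <- function(scen, amplitude, frequencies,
                               controls = simulation_controls()) {
  stopifnot(all(frequencies > 0))
  purrr::map_dfr(frequencies, function(f) {
    res <- .integrate(scen, acoustic_drive(amplitude, f), controls,
                      save_trajectory = FALSE)
    ratio <- res$Rmax / scen$population$radii
    i <- which.max(ratio)
    tibble::tibble(frequency = f,
                   max_expansion_ratio = ratio[i],
                   argmax_radius = scen$population$radii[i],
                   status = if (res$status == 0) "completed" else "failed")
  })
}

#' Export a trajectory to CSV
#'
#' Columns `t, R_1..R_q, U_1..U_q`, written with 9 significant digits.
#'
#' @param traj A [run_simulation()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cav_trajectory"))
  df <- as.data.frame(lapply(traj, signif, digits = 9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
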