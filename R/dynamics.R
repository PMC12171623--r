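#' Acoustic drive signal
#'
#' Sinusoidal driving pressure `p_s(t) = -p_a sin(2 pi f t)`: the rarefaction
#' half-cycle comes first, so bubbles grow before the first compression.
#'
#' @param amplitude Pressure amplitude p_a (Pa), non-negative.
#' @param frequency Drive frequency f (Hz), positive.
#' @return An object of class `cav_drive`.
#' @export
acoustic_drive <- function(amplitude, frequency) {
  stopifnot(amplitude >= 0, frequency > 0)
  structure(list(amplitude = amplitude, frequency = frequency),
            class = "cav_drive")
}

#' Driving pressure and its time derivative
#'
#' @param drive An [acoustic_drive()].
#' @param t Time(s) in seconds (vectorised).
#' @return Pressure (Pa) or its rate (Pa/s).
#' @export
#' @examples
#' drive_pressure(acoustic_drive(100e3, 1e6), 0.25e-6)  # -100 kPa
drive_pressure <- function(drive, t) {
  -drive$amplitude * sin(2 * pi * drive$frequency * t)
}

#' @rdname drive_pressure
#' @export
drive_pressure_rate <- function(drive, t) {
  -drive$amplitude * 2 * pi * drive$frequency * cos(2 * pi * drive$frequency * t)
}

#' Liquid pressure at the bubble wall
#'
#' Wall pressure for one size class with a Kelvin-Voigt viscoelastic stress:
#' adiabatic gas pressure referenced to the rest state, minus ambient and
#' Laplace pressures, viscous stress `4 mu Rdot / R`, elastic stress
#' `(4G / 3R^3)(R^3 - R0^3)`, and the drive. At rest (`R = R0`, `Rdot = 0`,
#' no drive) it vanishes identically.
#'
#' @param R Instantaneous radius (m), positive.
#' @param Rdot Wall velocity (m/s).
#' @param R0 Rest radius (m).
#' @param med A [medium()].
#' @param gas A [gas_model()].
#' @param drive An [acoustic_drive()]; omit (or `NULL`) for no drive.
#' @param t Time (s).
#' @return Pressure p_i (Pa).
#' @export
boundary_pressure <- function(R, Rdot, R0, med, gas, drive = NULL, t = 0) {
  if (any(R <= 0)) stop("non-positive bubble radius (integrator blow-up?)")
  ps <- if (is.null(drive)) 0 else drive_pressure(drive, t)
  pg0 <- med$static_pressure - med$vapor_pressure + 2 * med$surface_tension / R0
  # grouped so the rest state cancels exactly in floating point
  pg0 * ((R0 / R)^(3 * gas$polytropic_exponent) - 1) +
    2 * med$surface_tension * (1 / R0 - 1 / R) -
    4 * med$viscosity * Rdot / R -
    (4 * med$shear_modulus / 3) * (1 - R0^3 / R^3) - ps
}

#' Analytic rate of the wall pressure
#'
#' Returns `dp_i/dt` split into a part that does not involve the wall
#' acceleration and the coefficient multiplying `Rddot` (which is
#' `-4 mu / R`, from the viscous stress; it is moved onto the left-hand side
#' of the acceleration system).
#'
#' @inheritParams boundary_pressure
#' @return A list with `explicit_rate` (Pa/s) and `acceleration_coefficient`
#'   (Pa s^2 / m, the factor of `Rddot`).
#' @export
boundary_pressure_rate <- function(R, Rdot, R0, med, gas, drive = NULL,
                                   t = 0) {
  if (any(R <= 0)) stop("non-positive bubble radius (integrator blow-up?)")
  dps <- if (is.null(drive)) 0 else drive_pressure_rate(drive, t)
  pg0 <- med$static_pressure - med$vapor_pressure + 2 * med$surface_tension / R0
  pgas <- pg0 * (R0 / R)^(3 * gas$polytropic_exponent)
  expl <- -3 * gas$polytropic_exponent * pgas * Rdot / R +
    2 * med$surface_tension * Rdot / R^2 +
    4 * med$viscosity * Rdot^2 / R^2 -
    4 * med$shear_modulus * R0^3 * Rdot / R^4 - dps
  list(explicit_rate = expl,
       acceleration_coefficient = -4 * med$viscosity / R)
}

#' Coupling-term prefactor (typography-parse switch)
#'
#' The bubble-bubble radiation coupling is taken as
#' `S_j * d(R_j^2 Rdot_j)/dt = S_j (2 R_j Rdot_j^2 + R_j^2 Rddot_j)`.
#' An alternative reading halves the whole term; set this constant to 0.5
#' for a sensitivity analysis.
#' @keywords internal
.coupling_prefactor <- 1.0

#' Wall accelerations of the coupled cluster
#'
#' Assembles and solves the q x q linear system for the wall accelerations
#' `Rddot_i` of all size classes at one instant. The system matrix is a
#' diagonal `d_i = (1 - Rdot_i/c_l) R_i + 4 mu/(rho c_l)` plus the rank-one
#' radiation-coupling update `1 s^T` with `s_j = S_j R_j^2`. Solved by the
#' Sherman-Morrison identity (default) or by a dense solve; the two agree to
#' machine precision and the dense route exists as a cross-check.
#'
#' @param R,Rdot Radii (m) and wall velocities (m/s), length q.
#' @param R0 Rest radii (m), length q.
#' @param S Coupling strengths S_j (1/m), length q (see
#'   [cluster_geometry()]).
#' @param med A [medium()]; `gas` a [gas_model()].
#' @param gas A [gas_model()].
#' @param drive An [acoustic_drive()] or `NULL`.
#' @param t Time (s).
#' @param method `"sherman_morrison"` or `"direct"`.
#' @return Wall accelerations (m/s^2), length q.
#' @export
assemble_accelerations <- function(R, Rdot, R0, S, med, gas, drive = NULL,
                                   t = 0,
                                   method = c("sherman_morrison", "direct")) {
  method <- match.arg(method)
  q <- length(R)
  stopifnot(length(Rdot) == q, length(R0) == q, length(S) == q)
  if (any(R <= 0)) stop("non-positive bubble radius (integrator blow-up?)")
  cl <- med$sound_speed; rho <- med$density
  p <- boundary_pressure(R, Rdot, R0, med, gas, drive, t)
  pr <- boundary_pressure_rate(R, Rdot, R0, med, gas, drive, t)
  d <- (1 - Rdot / cl) * R + 4 * med$viscosity / (rho * cl)
  if (any(abs(d) < 1e-300))
    stop("singular acceleration system: vanishing diagonal for class(es) ",
         paste(which(abs(d) < 1e-300), collapse = ", "))
  cpf <- .coupling_prefactor
  b <- (1 + Rdot / cl) * p / rho + R / (rho * cl) * pr$explicit_rate -
    1.5 * Rdot^2 * (1 - Rdot / (3 * cl)) - cpf * sum(S * 2 * R * Rdot^2)
  v <- cpf * S * R^2
  if (method == "direct") {
    M <- diag(d, q) + matrix(rep(v, each = q), q, q)
    return(drop(solve(M, b)))
  }
  denom <- 1 + sum(v / d)
  if (abs(denom) < 1e-14)
    stop("singular acceleration system: rank-one denominator vanished")
  b / d - (sum(v * b / d) / denom) / d
}

#' Adiabatic core temperature
#'
#' Temperature of the gas inside a bubble under adiabatic compression or
#' expansion from the rest state: `T = T0 (R0/R)^(3(kappa-1))`. Strictly
#' decreasing in `R` for `kappa > 1`; a deep collapse (`R << R0`) yields
#' thousands of kelvin.
#'
#' @param R Instantaneous radius (m), positive (vectorised).
#' @param R0 Rest radius (m).
#' @param gas A [gas_model()].
#' @return Temperature (K).
#' @export
#' @examples
#' bubble_temperature(0.5e-6, 1e-6, gas_model())  # ~666 K
bubble_temperature <- function(R, R0, gas) {
  if (any(R <= 0)) stop("non-positive bubble radius")
  gas$initial_temperature * (R0 / R)^(3 * (gas$polytropic_exponent - 1))
}
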