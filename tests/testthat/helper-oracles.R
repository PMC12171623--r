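# Independent oracles used across the suite.

# Scalar classical Keller-Miksis wall acceleration for a single decoupled
# bubble, written directly from the scalar equation (no vector/rank-one
# machinery): (1 - U/c) R Rdd + (3/2) U^2 (1 - U/(3c))
#   = (1 + U/c) p / rho + (R / (rho c)) dp/dt,
# with the Kelvin-Voigt wall pressure and the viscous dp/dt acceleration
# term moved to the left-hand side.
scalar_km_acceleration <- function(R, U, R0, med, gas, pa = 0, f = 1e6,
                                   t = 0) {
  p0 <- med$static_pressure; pv <- med$vapor_pressure
  sig <- med$surface_tension; mu <- med$viscosity; G <- med$shear_modulus
  rho <- med$density; c <- med$sound_speed; k <- gas$polytropic_exponent
  ps <- -pa * sin(2 * pi * f * t)
  dps <- -pa * 2 * pi * f * cos(2 * pi * f * t)
  pg <- (p0 - pv + 2 * sig / R0) * (R0 / R)^(3 * k)
  p <- pg - p0 + pv - 2 * sig / R - 4 * mu * U / R -
    (4 * G / (3 * R^3)) * (R^3 - R0^3) - ps
  dpdt_expl <- -3 * k * pg * U / R + 2 * sig * U / R^2 + 4 * mu * U^2 / R^2 -
    4 * G * R0^3 * U / R^4 - dps
  lhs_coef <- (1 - U / c) * R + 4 * mu / (rho * c)
  rhs <- (1 + U / c) * p / rho + R / (rho * c) * dpdt_expl -
    1.5 * U^2 * (1 - U / (3 * c))
  rhs / lhs_coef
}

# deSolve route for cross-checking the compiled integrator: the coupled
# system integrated with an independent solver (lsoda) on an R-level RHS
# built from the package's R implementation of the acceleration assembly.
desolve_trajectory <- function(scen, drive, times) {
  geo <- cluster_geometry(scen$population)
  q <- nrow(geo)
  rhs <- function(t, y, parms) {
    acc <- assemble_accelerations(y[1:q], y[(q + 1):(2 * q)], geo$radius,
                                  geo$coupling_strength, scen$medium,
                                  scen$gas, drive, t)
    list(c(y[(q + 1):(2 * q)], acc))
  }
  deSolve::ode(y = c(geo$radius, rep(0, q)), times = times, func = rhs,
               parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-14)
}

# Surface-tension-corrected linear (Minnaert) resonance frequency.
minnaert_frequency <- function(R0, med, gas) {
  p0 <- med$static_pressure; pv <- med$vapor_pressure
  sig <- med$surface_tension; k <- gas$polytropic_exponent
  w2 <- (3 * k * (p0 - pv + 2 * sig / R0) - 2 * sig / R0) / (med$density * R0^2)
  sqrt(w2) / (2 * pi)
}

# Exhaustive fine amplitude scan (step = tol), the brute-force threshold
# oracle against scan + bisection.
brute_force_threshold <- function(scen, frequency, criterion, controls,
                                  p_min, p_max, tol) {
  for (pa in seq(p_min, p_max, by = tol)) {
    r <- cavithresh:::.fires(scen, acoustic_drive(pa, frequency),
                             cavitation_criterion(criterion), controls)
    if (r$fired) return(pa)
  }
  NA_real_
}

water <- medium_preset("water")$medium
liver <- medium_preset("liver")$medium
gas <- gas_model()

# controls scaled for fast unit tests (short runs, early window)
fast_controls <- function(n_cycles = 20, window = c(10, 18), ...) {
  simulation_controls(n_cycles = n_cycles, window = window, ...)
}
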