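test_that("drive pressure is a negative sine with matching derivative", {
  d <- acoustic_drive(100e3, 1e6)
  expect_equal(drive_pressure(d, 0), 0)
  expect_equal(drive_pressure(d, 0.25e-6), -100e3)
  expect_equal(drive_pressure(acoustic_drive(0, 1e6), c(0, 1e-7, 3e-7)),
               c(0, 0, 0))
  # derivative against a central difference
  h <- 1e-12
  for (t in c(0.1e-6, 0.37e-6, 0.8e-6)) {
    expect_equal(drive_pressure_rate(d, t),
                 (drive_pressure(d, t + h) - drive_pressure(d, t - h)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("wall pressure vanishes at rest and matches hand evaluation", {
  expect_identical(boundary_pressure(1e-6, 0, 1e-6, water, gas), 0)
  # expanded bubble, R = 2 R0 in water
  expect_equal(boundary_pressure(2e-6, 0, 1e-6, water, gas), -1.58e5,
               tolerance = 1e-2)
  # at rest under a drive only the drive term survives
  d <- acoustic_drive(50e3, 1e6)
  t_peak <- 0.25e-6
  expect_equal(boundary_pressure(1e-6, 0, 1e-6, water, gas, d, t_peak),
               -drive_pressure(d, t_peak))
  expect_error(boundary_pressure(-1e-6, 0, 1e-6, water, gas),
               "non-positive")
})

test_that("analytic wall-pressure rate matches a finite-difference oracle", {
  # rest, no drive: every explicit term carries Rdot or dps/dt
  pr <- boundary_pressure_rate(1e-6, 0, 1e-6, water, gas)
  expect_equal(pr$explicit_rate, 0)
  # inviscid medium: no acceleration coupling in dp/dt
  inviscid <- medium(998, 1500, 0.0725, 1e-30, 0)
  expect_equal(
    boundary_pressure_rate(2e-6, 10, 1e-6, inviscid, gas)$acceleration_coefficient,
    0, tolerance = 1e-20)

  # synthetic path R(t) = R0 (1 + 0.3 sin wt): central-difference dp/dt
  # minus the analytically known acceleration contribution
  R0 <- 3e-6; w <- 2 * pi * 4e5
  d <- acoustic_drive(80e3, 5e5)
  path_R <- function(t) R0 * (1 + 0.3 * sin(w * t))
  path_U <- function(t) R0 * 0.3 * w * cos(w * t)
  path_A <- function(t) -R0 * 0.3 * w^2 * sin(w * t)
  for (med in list(water, liver)) {
    for (t in c(0.3e-6, 1.1e-6, 2.7e-6)) {
      h <- 1e-13
      p_of <- function(s) boundary_pressure(path_R(s), path_U(s), R0, med,
                                            gas, d, s)
      dp_num <- (p_of(t + h) - p_of(t - h)) / (2 * h)
      pr <- boundary_pressure_rate(path_R(t), path_U(t), R0, med, gas, d, t)
      dp_ana <- pr$explicit_rate + pr$acceleration_coefficient * path_A(t)
      expect_equal(dp_ana, dp_num, tolerance = 1e-6)
    }
  }
})

test_that("acceleration assembly matches the scalar oracle when decoupled", {
  set.seed(7)
  for (i in 1:25) {
    R0 <- stats::runif(1, 0.5, 10) * 1e-6
    R <- R0 * stats::runif(1, 0.3, 3)
    U <- stats::runif(1, -50, 50)
    med <- if (i %% 2) water else liver
    pa <- stats::runif(1, 0, 200e3); f <- stats::runif(1, 1e5, 2e6)
    t <- stats::runif(1, 0, 1e-6)
    a_pkg <- assemble_accelerations(R, U, R0, S = 0, med, gas,
                                    acoustic_drive(pa, f), t)
    a_orc <- scalar_km_acceleration(R, U, R0, med, gas, pa, f, t)
    expect_equal(a_pkg, a_orc, tolerance = 1e-12)
  }
})

test_that("coupled acceleration system solves exactly", {
  set.seed(11)
  geo <- cluster_geometry(default_cluster())
  for (rep in 1:10) {
    R <- geo$radius * stats::runif(6, 0.4, 2.5)
    U <- stats::runif(6, -100, 100)
    d <- acoustic_drive(150e3, 7e5)
    a_sm <- assemble_accelerations(R, U, geo$radius, geo$coupling_strength,
                                   water, gas, d, 1e-7)
    a_dir <- assemble_accelerations(R, U, geo$radius, geo$coupling_strength,
                                    water, gas, d, 1e-7, method = "direct")
    # Sherman-Morrison vs dense solve
    expect_equal(a_sm, a_dir, tolerance = 1e-12)
    # residual of the assembled system M a = b re-multiplied
    cl <- water$sound_speed; rho <- water$density
    p <- boundary_pressure(R, U, geo$radius, water, gas, d, 1e-7)
    pr <- boundary_pressure_rate(R, U, geo$radius, water, gas, d, 1e-7)
    dg <- (1 - U / cl) * R + 4 * water$viscosity / (rho * cl)
    v <- geo$coupling_strength * R^2
    b <- (1 + U / cl) * p / rho + R / (rho * cl) * pr$explicit_rate -
      1.5 * U^2 * (1 - U / (3 * cl)) -
      sum(geo$coupling_strength * 2 * R * U^2)
    M <- diag(dg) + matrix(rep(v, each = 6), 6, 6)
    expect_lt(max(abs(M %*% a_sm - b)) / max(abs(b)), 1e-12)
  }
})

test_that("equilibrium is an exact fixed point of the assembly", {
  geo <- cluster_geometry(default_cluster())
  a <- assemble_accelerations(geo$radius, rep(0, 6), geo$radius,
                              geo$coupling_strength, water, gas)
  expect_identical(a, rep(0, 6))
})

test_that("coupling switch: zero coupling decouples the classes", {
  geo <- cluster_geometry(default_cluster())
  R <- geo$radius * c(1.2, 0.8, 1.5, 0.9, 1.1, 0.7)
  U <- c(5, -3, 10, -8, 2, -1)
  d <- acoustic_drive(120e3, 5e5)
  a_joint <- assemble_accelerations(R, U, geo$radius, rep(0, 6), water, gas,
                                    d, 2e-7)
  a_sep <- vapply(1:6, function(i)
    assemble_accelerations(R[i], U[i], geo$radius[i], 0, water, gas, d, 2e-7),
    numeric(1))
  expect_equal(a_joint, a_sep, tolerance = 1e-14)
})

test_that("adiabatic core temperature follows the compression power law", {
  expect_equal(bubble_temperature(1e-6, 1e-6, gas), 290)
  expect_equal(bubble_temperature(1e-7, 1e-6, gas), 290 * 10^1.2,
               tolerance = 1e-12)
  expect_equal(bubble_temperature(2e-6, 1e-6, gas), 290 * 2^-1.2,
               tolerance = 1e-12)
  # strictly decreasing in R for kappa > 1
  Rs <- seq(0.2, 3, length.out = 50) * 1e-6
  expect_true(all(diff(bubble_temperature(Rs, 1e-6, gas)) < 0))
  expect_error(bubble_temperature(0, 1e-6, gas), "non-positive")
})
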