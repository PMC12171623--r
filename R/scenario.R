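#' Define an acoustic medium
#'
#' A medium is the liquid or soft tissue surrounding the bubbles. It is
#' described by its density, sound speed, surface tension at the bubble
#' wall, Kelvin-Voigt viscosity and shear modulus, ambient static pressure
#' and vapor pressure. Water is the `shear_modulus = 0` (Newtonian) limit.
#'
#' @param density Liquid density rho (kg/m^3).
#' @param sound_speed Sound speed in the liquid c_l (m/s).
#' @param surface_tension Surface tension sigma (N/m).
#' @param viscosity Dynamic viscosity mu (Pa s).
#' @param shear_modulus Kelvin-Voigt shear modulus G (Pa); 0 for a
#'   Newtonian liquid.
#' @param static_pressure Ambient static pressure p0 (Pa).
#' @param vapor_pressure Vapor pressure inside the bubble p_v (Pa); must be
#'   below `static_pressure`.
#' @param name Optional label carried through outputs.
#' @return An object of class `cav_medium` (a named list of SI constants).
#' @seealso [medium_preset()] for the built-in water and liver media.
#' @export
#' @examples
#' medium(density = 998, sound_speed = 1500, surface_tension = 0.0725,
#'        viscosity = 1e-3, shear_modulus = 0)
medium <- function(density, sound_speed, surface_tension, viscosity,
                   shear_modulus = 0, static_pressure = 101.3e3,
                   vapor_pressure = 2.33e3, name = "custom") {
  stopifnot(density > 0, sound_speed > 0, surface_tension > 0, viscosity > 0,
            shear_modulus >= 0, static_pressure > 0, vapor_pressure >= 0,
            vapor_pressure < static_pressure)
  structure(
    list(name = name, density = density, sound_speed = sound_speed,
         surface_tension = surface_tension, viscosity = viscosity,
         shear_modulus = shear_modulus, static_pressure = static_pressure,
         vapor_pressure = vapor_pressure),
    class = "cav_medium")
}

#' @export
print.cav_medium <- function(x, ...) {
  cat("<cav_medium> ", x$name, "\n", sep = "")
  cat(sprintf("  rho = %g kg/m^3, c_l = %g m/s, sigma = %g N/m\n",
              x$density, x$sound_speed, x$surface_tension))
  cat(sprintf("  mu = %g Pa.s, G = %g Pa, p0 = %g Pa, p_v = %g Pa\n",
              x$viscosity, x$shear_modulus, x$static_pressure,
              x$vapor_pressure))
  invisible(x)
}

#' Gas model inside the bubbles
#'
#' The bubble interior is an ideal gas compressed adiabatically, so a single
#' exponent `polytropic_exponent` relates pressure and temperature to the
#' bubble volume. The gas sound speed is used only by the wall-speed
#' cavitation criterion.
#'
#' @param polytropic_exponent Adiabatic exponent kappa (1.4 for a diatomic
#'   gas).
#' @param initial_temperature Rest temperature inside the bubble T0 (K).
#' @param sound_speed Sound speed of the gas c_g (m/s).
#' @return An object of class `cav_gas`.
#' @export
gas_model <- function(polytropic_exponent = 1.4, initial_temperature = 290,
                      sound_speed = 340) {
  stopifnot(polytropic_exponent > 1, initial_temperature > 0, sound_speed > 0)
  structure(list(polytropic_exponent = polytropic_exponent,
                 initial_temperature = initial_temperature,
                 sound_speed = sound_speed),
            class = "cav_gas")
}

#' Built-in medium presets
#'
#' Two reference media: degassed water and liver, the latter a soft
#' viscoelastic tissue with a Kelvin-Voigt shear modulus of 40 kPa.
#' Both share the ambient conditions p0 = 101.3 kPa, p_v = 2.33 kPa and the
#' adiabatic gas model (kappa = 1.4, T0 = 290 K, c_g = 340 m/s).
#'
#' @param name `"water"` or `"liver"`.
#' @return A list with elements `medium` (a [medium()]) and `gas`
#'   (a [gas_model()]).
#' @export
#' @examples
#' medium_preset("liver")$medium
medium_preset <- function(name = c("water", "liver")) {
  name <- match.arg(name)
  med <- switch(name,
    water = medium(density = 998, sound_speed = 1500,
                   surface_tension = 0.0725, viscosity = 1e-3,
                   shear_modulus = 0, name = "water"),
    liver = medium(density = 1060, sound_speed = 1549,
                   surface_tension = 0.056, viscosity = 9e-3,
                   shear_modulus = 40e3, name = "liver"))
  list(medium = med, gas = gas_model())
}

#' Bubble population of a cluster
#'
#' A cluster is a set of `q` discrete size classes inside a fixed cloud
#' volume. Each class `i` has rest radius `R0_i` and count `N_i`; its number
#' density `n_i = N_i / V` sets the mean bubble spacing and the mean-field
#' coupling strength between bubbles (see [cluster_geometry()]).
#'
#' @param radii Rest radii R0_i in meters, strictly increasing.
#' @param counts Bubble counts per class (non-negative; rounded to integers).
#' @param cloud_volume Cloud volume V (m^3). The default is a cube of side
#'   3 mm.
#' @return An object of class `cav_population`.
#' @export
#' @examples
#' bubble_population(radii = c(1, 5) * 1e-6, counts = c(1e5, 1e5))
bubble_population <- function(radii, counts, cloud_volume = 2.7e-8) {
  stopifnot(length(radii) >= 1, length(radii) == length(counts),
            all(radii > 0), all(diff(radii) > 0), all(counts >= 0),
            cloud_volume > 0)
  structure(list(radii = as.numeric(radii),
                 counts = round(as.numeric(counts)),
                 cloud_volume = cloud_volume),
            class = "cav_population")
}

#' @export
print.cav_population <- function(x, ...) {
  cat(sprintf("<cav_population> %d size class(es), V = %g m^3\n",
              length(x$radii), x$cloud_volume))
  print(cluster_geometry(x))
  invisible(x)
}

#' Default six-class bubble cluster
#'
#' The reference cluster: size classes \{0.5, 1, 3, 6, 8, 10\} micrometres
#' with the total bubble number split equally across classes (rounded to the
#' nearest integer per class) in a 2.7e-8 m^3 cloud.
#'
#' @param total_number Total number of bubbles in the cloud (default 4e5).
#' @param cloud_volume Cloud volume (m^3).
#' @return A [bubble_population()].
#' @export
#' @examples
#' default_cluster()
default_cluster <- function(total_number = 4e5, cloud_volume = 2.7e-8) {
  stopifnot(total_number >= 0)
  radii <- c(0.5, 1, 3, 6, 8, 10) * 1e-6
  bubble_population(radii, rep(round(total_number / 6), 6), cloud_volume)
}

#' Single-size cluster and single-bubble populations
#'
#' `same_radius_cluster()` keeps the full bubble count in one size class, so
#' bubble-bubble coupling stays active. `single_bubble()` is one bubble in
#' the cloud with coupling disabled (the classical single-bubble model).
#'
#' @param radius Rest radius R0 (m).
#' @param total_number Bubble count (same-radius model only).
#' @param cloud_volume Cloud volume (m^3).
#' @return A [bubble_population()]; for `single_bubble()` the object is
#'   additionally tagged so that [cluster_geometry()] returns zero coupling.
#' @export
same_radius_cluster <- function(radius, total_number = 4e5,
                                cloud_volume = 2.7e-8) {
  bubble_population(radius, total_number, cloud_volume)
}

#' @rdname same_radius_cluster
#' @export
single_bubble <- function(radius, cloud_volume = 2.7e-8) {
  pop <- bubble_population(radius, 1, cloud_volume)
  attr(pop, "decoupled") <- TRUE
  pop
}

#' Derived cluster geometry
#'
#' Per size class: number density `n_i = N_i / V`, mean bubble distance
#' `delta_r_i = n_i^(-1/3)`, and mean-field coupling strength
#' `S_i = 2 pi n_i^(1/3)` (the continuum sum of inverse distances to all
#' bubbles of the class). Empty classes have zero coupling and infinite mean
#' distance. For populations built with [single_bubble()] all couplings are
#' forced to zero.
#'
#' @param pop A [bubble_population()].
#' @return A tibble with columns `radius`, `count`, `number_density`,
#'   `mean_distance`, `coupling_strength`.
#' @export
#' @examples
#' cluster_geometry(default_cluster())
cluster_geometry <- function(pop) {
  stopifnot(inherits(pop, "cav_population"))
  n <- pop$counts / pop$cloud_volume
  S <- 2 * pi * n^(1 / 3)
  if (isTRUE(attr(pop, "decoupled"))) S <- rep(0, length(S))
  tibble::tibble(
    radius = pop$radii,
    count = pop$counts,
    number_density = n,
    mean_distance = ifelse(n > 0, n^(-1 / 3), Inf),
    coupling_strength = S)
}

#' Model validity report
#'
#' Checks the assumptions of the mean-field cluster model at a given drive
#' frequency: the void fraction (total bubble volume over cloud volume) must
#' stay below 5% to avoid acoustic shielding, and the mean bubble distance
#' of every class must stay below one eighth of the acoustic wavelength so
#' that bubbles of a class vibrate in phase. Violations are reported (and
#' raised as warnings), never turned into errors: marginal configurations
#' are still simulated.
#'
#' @param pop A [bubble_population()].
#' @param med A [medium()].
#' @param frequency Drive frequency (Hz).
#' @param quiet Suppress warnings on violated limits.
#' @return A list of class `cav_validity`: `void_fraction`,
#'   `void_fraction_ok`, `wavelength_over_8`, `per_class` (tibble with
#'   `radius`, `mean_distance`, `distance_ok`), `notes`.
#' @export
#' @examples
#' validity_check(default_cluster(), medium_preset("water")$medium, 500e3)
validity_check <- function(pop, med, frequency, quiet = FALSE) {
  stopifnot(inherits(pop, "cav_population"), inherits(med, "cav_medium"),
            frequency > 0)
  vf <- (4 * pi / 3) * sum(pop$counts * pop$radii^3) / pop$cloud_volume
  lam8 <- med$sound_speed / frequency / 8
  geo <- cluster_geometry(pop)
  per_class <- tibble::tibble(
    radius = geo$radius,
    mean_distance = geo$mean_distance,
    distance_ok = geo$mean_distance < lam8 | geo$count == 0)
  notes <- character()
  if (vf > 0.05)
    notes <- c(notes, sprintf(
      "void fraction %.3g exceeds the 5%% shielding limit", vf))
  if (any(!per_class$distance_ok))
    notes <- c(notes, sprintf(
      "mean bubble distance exceeds lambda/8 = %.3g m for classes: %s",
      lam8, paste(format(per_class$radius[!per_class$distance_ok]),
                  collapse = ", ")))
  if (!quiet) for (msg in notes) warning(msg, call. = FALSE)
  structure(list(void_fraction = vf, void_fraction_ok = vf <= 0.05,
                 wavelength_over_8 = lam8, per_class = per_class,
                 notes = notes),
            class = "cav_validity")
}

#' @export
print.cav_validity <- function(x, ...) {
  cat(sprintf("<cav_validity> void fraction %.4g%% (%s), lambda/8 = %.3g m\n",
              100 * x$void_fraction,
              if (x$void_fraction_ok) "ok" else "EXCEEDS 5% limit",
              x$wavelength_over_8))
  print(x$per_class)
  invisible(x)
}

#' Bundle a full simulation scenario
#'
#' Combines the medium, gas model and bubble population into one object
#' consumed by [run_simulation()] and the threshold searches.
#'
#' @param med A [medium()] or a preset name (`"water"`, `"liver"`).
#' @param pop A [bubble_population()] (default: [default_cluster()]).
#' @param gas A [gas_model()].
#' @return An object of class `cav_scenario`.
#' @export
#' @examples
#' scenario("water")
#' scenario(medium_preset("liver")$medium, same_radius_cluster(6e-6))
scenario <- function(med = "water", pop = default_cluster(),
                     gas = gas_model()) {
  if (is.character(med)) med <- medium_preset(med)$medium
  stopifnot(inherits(med, "cav_medium"), inherits(pop, "cav_population"),
            inherits(gas, "cav_gas"))
  structure(list(medium = med, gas = gas, population = pop),
            class = "cav_scenario")
}

#' @export
print.cav_scenario <- function(x, ...) {
  cat("<cav_scenario>\n")
  print(x$medium)
  cat(sprintf("  gas: kappa = %g, T0 = %g K, c_g = %g m/s\n",
              x$gas$polytropic_exponent, x$gas$initial_temperature,
              x$gas$sound_speed))
  geo <- cluster_geometry(x$population)
  cat(sprintf("  cluster: %d class(es), radii %s um, total N = %g\n",
              nrow(geo), paste(format(geo$radius * 1e6), collapse = "/"),
              sum(geo$count)))
  invisible(x)
}
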