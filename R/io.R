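# Configuration handling, canonical fixtures and result serialization.
# Configs use field units (um, kHz, kPa, mPa.s); everything internal is SI.

#' Load a scenario configuration
#'
#' Reads a YAML (or JSON) configuration and resolves it to a fully specified
#' SI scenario plus drive and integration controls, filling defaults from
#' the built-in presets. Keys carry explicit unit suffixes in the field's
#' customary units and are converted at this boundary:
#'
#' ```yaml
#' medium: water            # or liver, or a mapping of explicit constants
#' population:
#'   total_number: 4.0e5    # default cluster; or radii_um: [...] + counts
#' drive:
#'   f_kHz: 500
#'   pa_kPa: 100            # optional (threshold searches set it)
#' simulation:
#'   n_cycles: 60
#'   window: [35, 55]
#' criterion: r2
#' ```
#'
#' @param path Path to the configuration file.
#' @return A list with elements `scenario`, `drive` (or `NULL` when no
#'   amplitude is given), `controls`, `criterion`.
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg),
                 c("medium", "gas", "population", "drive", "simulation",
                   "criterion"))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))

  med <- cfg$medium %||% "water"
  if (is.character(med)) {
    med <- medium_preset(med)$medium
  } else {
    req <- c("rho_kg_m3", "cl_m_s", "sigma_N_m", "mu_mPa_s")
    miss <- setdiff(req, names(med))
    if (length(miss))
      stop("explicit medium needs unit-suffixed keys: ",
           paste(miss, collapse = ", "))
    med <- medium(density = .num(med$rho_kg_m3),
                  sound_speed = .num(med$cl_m_s),
                  surface_tension = .num(med$sigma_N_m),
                  viscosity = .num(med$mu_mPa_s) * 1e-3,
                  shear_modulus = .num(med$G_kPa %||% 0) * 1e3,
                  static_pressure = .num(med$p0_kPa %||% 101.3) * 1e3,
                  vapor_pressure = .num(med$pv_kPa %||% 2.33) * 1e3)
  }
  gas <- if (is.null(cfg$gas)) gas_model() else
    gas_model(polytropic_exponent = .num(cfg$gas$kappa %||% 1.4),
              initial_temperature = .num(cfg$gas$T0_K %||% 290),
              sound_speed = .num(cfg$gas$cg_m_s %||% 340))
  popc <- cfg$population
  pop <- if (is.null(popc)) {
    default_cluster()
  } else if (!is.null(popc$radii_um)) {
    if (any(.num(popc$radii_um) <= 0)) stop("radii_um must be positive")
    bubble_population(.num(popc$radii_um) * 1e-6, .num(popc$counts),
                      .num(popc$cloud_volume_m3 %||% 2.7e-8))
  } else {
    default_cluster(.num(popc$total_number %||% 4e5),
                    .num(popc$cloud_volume_m3 %||% 2.7e-8))
  }
  if (is.null(cfg$drive$f_kHz)) stop("config must set drive: f_kHz")
  drv <- if (is.null(cfg$drive$pa_kPa)) NULL else
    acoustic_drive(.num(cfg$drive$pa_kPa) * 1e3, .num(cfg$drive$f_kHz) * 1e3)
  sim <- cfg$simulation
  controls <- simulation_controls(
    n_cycles = .num(sim$n_cycles %||% 60),
    window = .num(sim$window %||% c(35, 55)),
    rtol = .num(sim$rtol %||% 1e-8))
  list(scenario = scenario(med, pop, gas),
       drive = drv, frequency = .num(cfg$drive$f_kHz) * 1e3,
       controls = controls,
       criterion = cavitation_criterion(cfg$criterion %||% "r2"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 parses "4.0e5" (no signed exponent) as a string; accept it.
.num <- function(x) {
  if (is.null(x)) return(NULL)
  y <- suppressWarnings(as.numeric(unlist(x)))
  if (any(is.na(y))) stop("non-numeric value in config: ", toString(unlist(x)))
  y
}

#' Canonical study fixtures
#'
#' Named scenario bundles used throughout the parameter studies:
#' `multi_radii_<medium>` is the default six-class cluster;
#' `same_radius_<R0um>um_<medium>` keeps the full bubble count in one class
#' (coupling active); `single_<R0um>um_<medium>` is one decoupled bubble.
#'
#' @param name Fixture name, e.g. `"multi_radii_water"`,
#'   `"same_radius_10um_water"`, `"single_6um_liver"`.
#' @return A [scenario()].
#' @export
#' @examples
#' make_fixture("single_6um_liver")
make_fixture <- function(name) {
  m <- regmatches(name, regexec(
    "^(multi_radii|same_radius_([0-9.]+)um|single_([0-9.]+)um)_(water|liver)$",
    name))[[1]]
  if (!length(m)) stop("unknown fixture name: ", name)
  med <- m[5]
  pop <- if (m[2] == "multi_radii") default_cluster()
         else if (startsWith(m[2], "same_radius"))
           same_radius_cluster(as.numeric(m[3]) * 1e-6)
         else single_bubble(as.numeric(m[4]) * 1e-6)
  scenario(med, pop)
}

#' Write a threshold curve to CSV
#'
#' Columns `f_Hz, p_thresh_Pa, criterion, cavitating_radii_um`; floats with
#' 9 significant digits, deterministic column order, and a JSON manifest of
#' the run alongside.
#'
#' @param curve A [threshold_vs_frequency()] result.
#' @param path Output CSV path.
#' @param manifest Also write `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_threshold_csv <- function(curve, path, manifest = TRUE) {
  df <- data.frame(
    f_Hz = signif(curve$frequency, 9),
    p_thresh_Pa = signif(curve$threshold, 9),
    criterion = curve$criterion,
    cavitating_radii_um = vapply(
      curve$cavitating_radii,
      function(r) paste(signif(r * 1e6, 6), collapse = ";"), character(1)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (manifest) .write_manifest(paste0(path, ".manifest.json"))
  invisible(path)
}

#' Read back a threshold-curve CSV
#'
#' @param path CSV written by [write_threshold_csv()].
#' @return A tibble with the serialized columns.
#' @export
read_threshold_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a power-law fit report to JSON
#'
#' @param fit A [fit_power_law()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(A = fit$A, alpha = fit$alpha, B = fit$B,
         residual = fit$residual_norm,
         f_range_Hz = fit$frequency_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Run manifest: everything in the pipeline is deterministic (no random
# number use anywhere), so a manifest plus config reproduces outputs
# bit-for-bit up to floating-point determinism.
.write_manifest <- function(path, warnings = character()) {
  jsonlite::write_json(
    list(package = "cavithresh",
         version = as.character(utils::packageVersion("cavithresh")),
         deterministic = TRUE,
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
         warnings = warnings),
    path, auto_unbox = TRUE)
  invisible(path)
}
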