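# Amplitude threshold search, frequency sweeps, power-law fitting and the
# parameter-study drivers.

# Does the criterion fire at this amplitude?  Integrator failure during a
# violent collapse is handled here: maxima accumulated up to the failure are
# checked first; a failure with nothing fired gets one retry at 10x tighter
# tolerance, after which a still-failing, still-silent run is classified
# inconclusive and treated as cavitated for bracketing purposes (step
# collapse accompanies violent inertial collapse).
.fires <- function(scen, drive, criterion, controls) {
  run_once <- function(rtol) {
    res <- .integrate(scen, drive, controls, save_trajectory = FALSE,
                      rtol = rtol)
    R0 <- scen$population$radii
    usable <- isTRUE(res$window_touched)
    summ <- structure(
      tibble::tibble(radius = R0,
                     max_expansion_ratio = res$Rmax / R0,
                     max_wall_speed = res$Umax,
                     min_radius = res$Rmin,
                     max_temperature = bubble_temperature(res$Rmin, R0,
                                                          scen$gas)),
      class = c("cav_summary", "tbl_df", "tbl", "data.frame"),
      usable = usable, partial = res$status != 0, status = res$status)
    list(res = res, summary = summ, usable = usable)
  }
  r1 <- run_once(controls$rtol)
  if (r1$usable) {
    v <- evaluate_criterion(r1$summary, criterion, scen$medium, scen$gas)
    if (isTRUE(v$cluster_cavitated))
      return(list(fired = TRUE, inconclusive = FALSE,
                  cavitating_radii = v$cavitating_radii))
    if (r1$res$status == 0)
      return(list(fired = FALSE, inconclusive = FALSE,
                  cavitating_radii = numeric()))
  }
  # failed without firing: one retry at tighter tolerance
  r2 <- run_once(controls$rtol / 10)
  if (r2$usable) {
    v <- evaluate_criterion(r2$summary, criterion, scen$medium, scen$gas)
    if (isTRUE(v$cluster_cavitated))
      return(list(fired = TRUE, inconclusive = FALSE,
                  cavitating_radii = v$cavitating_radii))
    if (r2$res$status == 0)
      return(list(fired = FALSE, inconclusive = FALSE,
                  cavitating_radii = numeric()))
  }
  list(fired = TRUE, inconclusive = TRUE, cavitating_radii = numeric())
}

#' Minimum-amplitude cavitation threshold at one frequency
#'
#' Finds the lowest drive amplitude at which the chosen criterion fires in
#' any size class, using a coarse upward amplitude scan followed by
#' bisection of the first firing bracket. The coarse scan guards against
#' the response being non-monotone in amplitude (a pure bisection from the
#' ceiling could skip a lower firing amplitude).
#'
#' @param scen A [scenario()].
#' @param frequency Drive frequency (Hz).
#' @param criterion A [cavitation_criterion()] or kind string (default
#'   `"r2"`).
#' @param controls A [simulation_controls()].
#' @param p_min,p_max Scan floor and ceiling (Pa); defaults 10 kPa and
#'   6 MPa.
#' @param coarse_step Coarse scan step (Pa); default 10 kPa.
#' @param tol Bisection tolerance on the amplitude (Pa); default 1 kPa.
#' @return An object of class `cav_threshold`: a list with `frequency`,
#'   `threshold` (Pa; `NA` if nothing fired below `p_max`), `criterion`,
#'   `cavitating_radii` at the threshold, `above_ceiling`,
#'   `n_simulations`, `inconclusive_seen` and the search `trace` tibble.
#' @export
#' @examples
#' \donttest{
#' scen <- scenario("water", single_bubble(1e-6))
#' find_threshold(scen, 500e3, "r2", coarse_step = 25e3, tol = 5e3)
#' }
find_threshold <- function(scen, frequency, criterion = "r2",
                           controls = simulation_controls(),
                           p_min = 10e3, p_max = 6e6, coarse_step = 10e3,
                           tol = 1e3) {
  stopifnot(inherits(scen, "cav_scenario"), frequency > 0,
            p_min < p_max, coarse_step > 0, tol > 0)
  if (is.character(criterion)) criterion <- cavitation_criterion(criterion)
  trace <- list()
  n_sim <- 0L
  inconclusive_seen <- FALSE
  probe <- function(pa, stage) {
    r <- .fires(scen, acoustic_drive(pa, frequency), criterion, controls)
    n_sim <<- n_sim + 1L
    inconclusive_seen <<- inconclusive_seen || r$inconclusive
    trace[[length(trace) + 1L]] <<-
      tibble::tibble(amplitude = pa, fired = r$fired, stage = stage,
                     inconclusive = r$inconclusive)
    r
  }

  # coarse upward scan
  grid <- seq(p_min, p_max, by = coarse_step)
  if (grid[length(grid)] < p_max) grid <- c(grid, p_max)
  hit <- NULL
  lo <- NA_real_
  for (pa in grid) {
    r <- probe(pa, "scan")
    if (r$fired) { hit <- list(pa = pa, r = r); break }
    lo <- pa
  }
  done <- function(threshold, radii, ceiling) {
    structure(list(frequency = frequency, threshold = threshold,
                   criterion = criterion, cavitating_radii = radii,
                   above_ceiling = ceiling, n_simulations = n_sim,
                   inconclusive_seen = inconclusive_seen,
                   trace = dplyr::bind_rows(trace)),
              class = "cav_threshold")
  }
  if (is.null(hit)) return(done(NA_real_, numeric(), TRUE))
  hi <- hit$pa; radii_hi <- hit$r$cavitating_radii
  if (is.na(lo)) lo <- 0  # fired already at the scan floor
  # bisection on the first firing bracket
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    r <- probe(mid, "bisect")
    if (r$fired) { hi <- mid; radii_hi <- r$cavitating_radii } else lo <- mid
  }
  done(hi, radii_hi, FALSE)
}

#' @export
print.cav_threshold <- function(x, ...) {
  cat(sprintf("<cav_threshold> f = %g kHz, criterion %s\n",
              x$frequency / 1e3, x$criterion$kind))
  if (x$above_ceiling) {
    cat("  no firing amplitude below the search ceiling\n")
  } else {
    cat(sprintf("  threshold = %.1f kPa (%d simulations)\n",
                x$threshold / 1e3, x$n_simulations))
    if (length(x$cavitating_radii))
      cat("  cavitating classes (um):",
          paste(format(x$cavitating_radii * 1e6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Threshold-versus-frequency sweep
#'
#' Runs [find_threshold()] over a frequency grid and returns the threshold
#' curve with the cavitating classes at each point. At low frequencies the
#' large bubbles of the cluster fire first; towards the megahertz range the
#' small classes take over and the threshold climbs.
#'
#' @inheritParams find_threshold
#' @param frequencies Frequency grid (Hz).
#' @param ... Passed to [find_threshold()] (`p_min`, `p_max`, `coarse_step`,
#'   `tol`).
#' @return A tibble of class `cav_threshold_curve` with columns `frequency`,
#'   `threshold` (Pa), `criterion`, `cavitating_radii` (list column),
#'   `above_ceiling`, `inconclusive`.
#' @export
threshold_vs_frequency <- function(scen, frequencies, criterion = "r2",
                                   controls = simulation_controls(), ...) {
  if (is.character(criterion)) criterion <- cavitation_criterion(criterion)
  rows <- purrr::map(frequencies, function(f) {
    th <- find_threshold(scen, f, criterion, controls, ...)
    tibble::tibble(frequency = f, threshold = th$threshold,
                   criterion = criterion$kind,
                   cavitating_radii = list(th$cavitating_radii),
                   above_ceiling = th$above_ceiling,
                   inconclusive = th$inconclusive_seen)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cav_threshold_curve", class(out)))
}

#' Evaluate the power law P = A f^alpha + B
#'
#' @param A,alpha,B Power-law coefficients (P in Pa, f in Hz).
#' @param frequency Frequency (Hz), vectorised.
#' @return Threshold pressure (Pa).
#' @export
#' @examples
#' eval_power_law(7.58, 0.83, 9e4, 5e6) / 1e3  # ~2843 kPa
eval_power_law <- function(A, alpha, B, frequency) {
  A * frequency^alpha + B
}

#' Fit the power law P = A f^alpha + B to a threshold curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the linear pressure
#' scale with P in Pa and f in Hz, multi-started over alpha in
#' \{0.5, 0.75, 1.0\} (A and B seeded by ordinary least squares at each
#' fixed alpha); the best-residual fit is kept. alpha is constrained to
#' (0, 2).
#'
#' @param curve A [threshold_vs_frequency()] result, or any data frame with
#'   columns `frequency` (Hz) and `threshold` (Pa); rows flagged
#'   `above_ceiling` are dropped.
#' @param starts Initial values of alpha for the multi-start.
#' @return An object of class `cav_powerlaw` with coefficients `A`, `alpha`,
#'   `B`, the residual norm, the fitted frequency range and the data;
#'   supports [generics::tidy()], [generics::glance()], `predict()` and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' f <- 10^seq(4.5, 6.4, length.out = 12)
#' curve <- data.frame(frequency = f, threshold = eval_power_law(7.58, 0.83, 9e4, f))
#' coef(fit_power_law(curve))
fit_power_law <- function(curve, starts = c(0.5, 0.75, 1.0)) {
  df <- as.data.frame(curve)
  if ("above_ceiling" %in% names(df)) df <- df[!df$above_ceiling, ]
  df <- df[is.finite(df$frequency) & is.finite(df$threshold), ]
  if (nrow(df) < 5)
    stop("need at least 5 finite curve points to fit the power law")
  if (max(df$frequency) / min(df$frequency) < 10)
    warning("frequency span below one decade; fitted exponent is fragile",
            call. = FALSE)
  best <- NULL
  errs <- character()
  for (a0 in starts) {
    lin <- stats::lm(threshold ~ I(frequency^a0), data = df)
    A0 <- max(unname(stats::coef(lin)[2]), 1e-8)
    B0 <- unname(stats::coef(lin)[1])
    fit <- tryCatch(
      minpack.lm::nlsLM(threshold ~ A * frequency^alpha + B, data = df,
                        start = list(A = A0, alpha = a0, B = B0),
                        lower = c(A = 0, alpha = 1e-6, B = -Inf),
                        upper = c(A = Inf, alpha = 2, B = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) { errs <- c(errs, conditionMessage(fit)); next }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("power-law fit failed from all starts: ",
         paste(unique(errs), collapse = "; "))
  cf <- stats::coef(best$fit)
  structure(list(A = unname(cf["A"]), alpha = unname(cf["alpha"]),
                 B = unname(cf["B"]), residual_norm = sqrt(best$rss),
                 frequency_range = range(df$frequency),
                 n = nrow(df), data = tibble::as_tibble(df),
                 fit = best$fit),
            class = "cav_powerlaw")
}

#' @export
coef.cav_powerlaw <- function(object, ...) {
  c(A = object$A, alpha = object$alpha, B = object$B)
}

#' @export
predict.cav_powerlaw <- function(object, frequency = NULL, ...) {
  if (is.null(frequency)) frequency <- object$data$frequency
  eval_power_law(object$A, object$alpha, object$B, frequency)
}

#' @export
print.cav_powerlaw <- function(x, ...) {
  cat(sprintf(
    "<cav_powerlaw> P = %.4g f^%.3f + %.4g  (P in Pa, f in Hz)\n",
    x$A, x$alpha, x$B))
  cat(sprintf("  residual norm %.3g Pa over %d points, f in [%g, %g] kHz\n",
              x$residual_norm, x$n, x$frequency_range[1] / 1e3,
              x$frequency_range[2] / 1e3))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cav_powerlaw <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("A", "alpha", "B"),
                 estimate = c(x$A, x$alpha, x$B),
                 std.error = sm[c("A", "alpha", "B"), "Std. Error"])
}

#' @export
glance.cav_powerlaw <- function(x, ...) {
  tibble::tibble(residual.norm = x$residual_norm, nobs = x$n,
                 f.min = x$frequency_range[1], f.max = x$frequency_range[2])
}

# population with a prescribed share Q in one target class, remainder split
# equally over the other default classes
.composition_cluster <- function(target_radius, Q, total_number = 4e5,
                                 cloud_volume = 2.7e-8) {
  stopifnot(Q >= 0, Q <= 1)
  radii <- c(0.5, 1, 3, 6, 8, 10) * 1e-6
  i <- which(abs(radii - target_radius) < 1e-12)
  if (!length(i)) stop("target_radius must be one of the default classes")
  counts <- rep(round(total_number * (1 - Q) / (length(radii) - 1)),
                length(radii))
  counts[i] <- round(total_number * Q)
  bubble_population(radii, counts, cloud_volume)
}

#' Cluster-composition study
#'
#' Varies the share `Q` of one size class in the default cluster (total
#' bubble number fixed; the other five classes split the remainder equally)
#' and computes the threshold curve in both water and the viscoelastic
#' medium.
#'
#' @param target_radius Radius of the enriched class (m), one of the default
#'   classes.
#' @param Q Share of the total number in the target class, in `[0, 1]`.
#' @param frequencies Frequency grid (Hz).
#' @param criterion Criterion kind (default `"r2"`).
#' @param total_number Total bubble count (default 4e5).
#' @param controls A [simulation_controls()].
#' @param ... Passed to [find_threshold()].
#' @return A tibble of class `cav_threshold_curve` with an extra `medium`
#'   column (`"water"` / `"liver"`) and attribute `Q`.
#' @export
composition_study <- function(target_radius, Q, frequencies,
                              criterion = "r2", total_number = 4e5,
                              controls = simulation_controls(), ...) {
  pop <- .composition_cluster(target_radius, Q, total_number)
  rows <- purrr::map(c("water", "liver"), function(m) {
    cur <- threshold_vs_frequency(scenario(m, pop), frequencies, criterion,
                                  controls, ...)
    dplyr::mutate(cur, medium = m, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "Q") <- Q
  structure(out, class = c("cav_threshold_curve", class(out)))
}

#' Threshold map over shear modulus and viscosity
#'
#' Holds density, sound speed and surface tension at the viscoelastic-medium
#' values and varies only the Kelvin-Voigt parameters `(G, mu)`, computing
#' the threshold at a fixed frequency for every grid cell.
#'
#' @param pop A [bubble_population()].
#' @param shear_moduli Grid of shear moduli G (Pa).
#' @param viscosities Grid of viscosities mu (Pa s).
#' @param frequency Drive frequency (Hz).
#' @param criterion Criterion kind (default `"r2"`).
#' @param controls A [simulation_controls()].
#' @param base_medium Template medium providing the non-varied constants
#'   (default the liver preset).
#' @param ... Passed to [find_threshold()].
#' @return A tibble of class `cav_parameter_map` with columns
#'   `shear_modulus`, `viscosity`, `threshold`, `above_ceiling`.
#' @export
viscoelastic_map <- function(pop, shear_moduli, viscosities, frequency,
                             criterion = "r2",
                             controls = simulation_controls(),
                             base_medium = medium_preset("liver")$medium,
                             ...) {
  stopifnot(all(shear_moduli >= 0), all(viscosities > 0))
  grid <- expand.grid(shear_modulus = shear_moduli,
                      viscosity = viscosities)
  rows <- purrr::pmap(grid, function(shear_modulus, viscosity) {
    med <- medium(density = base_medium$density,
                  sound_speed = base_medium$sound_speed,
                  surface_tension = base_medium$surface_tension,
                  viscosity = viscosity, shear_modulus = shear_modulus,
                  static_pressure = base_medium$static_pressure,
                  vapor_pressure = base_medium$vapor_pressure,
                  name = "viscoelastic-grid")
    th <- find_threshold(scenario(med, pop), frequency, criterion, controls,
                         ...)
    tibble::tibble(shear_modulus = shear_modulus, viscosity = viscosity,
                   threshold = th$threshold,
                   above_ceiling = th$above_ceiling)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cav_parameter_map", class(out)),
            frequency = frequency)
}

#' Threshold versus total bubble number
#'
#' Sweeps the total bubble count at fixed frequency for either the default
#' multi-radii cluster or a same-radius cluster, in water by default. Small
#' same-radius bubbles are nearly insensitive to the count (their void
#' fraction stays tiny, so coupling is weak); the multi-radii cluster rises
#' with count up to a few hundred thousand bubbles and then flattens.
#'
#' @param total_numbers Grid of total bubble counts.
#' @param frequency Drive frequency (Hz).
#' @param criterion Criterion kind (default `"r2"`).
#' @param model `"multi_radii"` or `"same_radius"`.
#' @param radius Rest radius for the same-radius model (m).
#' @param med A [medium()] or preset name (default `"water"`).
#' @param controls A [simulation_controls()].
#' @param ... Passed to [find_threshold()].
#' @return A tibble of class `cav_parameter_map` with columns
#'   `total_number`, `threshold`, `above_ceiling`.
#' @export
number_study <- function(total_numbers, frequency, criterion = "r2",
                         model = c("multi_radii", "same_radius"),
                         radius = NULL, med = "water",
                         controls = simulation_controls(), ...) {
  model <- match.arg(model)
  if (model == "same_radius" && is.null(radius))
    stop("the same-radius model needs a `radius`")
  rows <- purrr::map(total_numbers, function(N) {
    pop <- if (model == "multi_radii") default_cluster(N)
           else same_radius_cluster(radius, N)
    th <- find_threshold(scenario(med, pop), frequency, criterion, controls,
                         ...)
    tibble::tibble(total_number = N, threshold = th$threshold,
                   above_ceiling = th$above_ceiling)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cav_parameter_map", class(out)),
            frequency = frequency, model = model)
}
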