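#' Cavitation criteria
#'
#' Five standard inertial-cavitation onset criteria, evaluated per size
#' class on its own window maxima:
#' \describe{
#'   \item{`r2`}{expansion ratio `R_max >= 2 R0`}
#'   \item{`ucl`}{wall speed reaches the liquid sound speed, `U_max >= c_l`}
#'   \item{`ucg`}{wall speed reaches the gas sound speed, `U_max >= c_g`}
#'   \item{`t1550`}{adiabatic core temperature `T_max >= 1550 K`}
#'   \item{`t5000`}{adiabatic core temperature `T_max >= 5000 K`}
#' }
#' The cluster is deemed cavitating as soon as *any* size class fires.
#'
#' @param kind One of `"r2"`, `"ucl"`, `"ucg"`, `"t1550"`, `"t5000"`.
#' @return An object of class `cav_criterion`.
#' @export
cavitation_criterion <- function(kind = c("r2", "ucl", "ucg", "t1550",
                                          "t5000")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "cav_criterion")
}

#' @export
print.cav_criterion <- function(x, ...) {
  lab <- switch(x$kind,
                r2 = "R_max >= 2 R0", ucl = "U_max >= c_l",
                ucg = "U_max >= c_g", t1550 = "T_max >= 1550 K",
                t5000 = "T_max >= 5000 K")
  cat("<cav_criterion> ", lab, "\n", sep = "")
  invisible(x)
}

#' Evaluate a cavitation criterion on a window summary
#'
#' Compares each size class's window maximum against the criterion constant
#' and aggregates with the any-class rule. An unusable summary (trajectory
#' failed before the window) gives an inconclusive verdict.
#'
#' @param summary A [summarize_window()] result.
#' @param criterion A [cavitation_criterion()] or its kind string.
#' @param med A [medium()] (needed for the `ucl` criterion).
#' @param gas A [gas_model()] (needed for the `ucg` criterion).
#' @return A list of class `cav_verdict`: `per_class` (tibble `radius`,
#'   `value`, `threshold`, `fired`), `cluster_cavitated`,
#'   `cavitating_radii`, `inconclusive`.
#' @export
evaluate_criterion <- function(summary, criterion, med, gas = gas_model()) {
  if (is.character(criterion)) criterion <- cavitation_criterion(criterion)
  stopifnot(inherits(summary, "cav_summary"),
            inherits(criterion, "cav_criterion"))
  if (!isTRUE(attr(summary, "usable"))) {
    return(structure(list(per_class = NULL, cluster_cavitated = NA,
                          cavitating_radii = numeric(), inconclusive = TRUE),
                     class = "cav_verdict"))
  }
  spec <- switch(criterion$kind,
    r2    = list(value = summary$max_expansion_ratio, threshold = 2),
    ucl   = list(value = summary$max_wall_speed, threshold = med$sound_speed),
    ucg   = list(value = summary$max_wall_speed, threshold = gas$sound_speed),
    t1550 = list(value = summary$max_temperature, threshold = 1550),
    t5000 = list(value = summary$max_temperature, threshold = 5000))
  fired <- spec$value >= spec$threshold
  per_class <- tibble::tibble(radius = summary$radius, value = spec$value,
                              threshold = spec$threshold, fired = fired)
  structure(list(per_class = per_class,
                 cluster_cavitated = any(fired),
                 cavitating_radii = summary$radius[fired],
                 inconclusive = FALSE),
            class = "cav_verdict")
}

#' @export
print.cav_verdict <- function(x, ...) {
  if (isTRUE(x$inconclusive)) {
    cat("<cav_verdict> inconclusive (unusable window summary)\n")
  } else {
    cat("<cav_verdict> cluster cavitated:", x$cluster_cavitated, "\n")
    if (length(x$cavitating_radii))
      cat("  firing classes (um):",
          paste(format(x$cavitating_radii * 1e6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Blake threshold of a gas nucleus
#'
#' Quasi-static critical pressure for explosive growth of a free gas
#' nucleus of rest radius `R0`: the balance of static pressure against
#' surface tension, independent of frequency. Two conventional variants are
#' provided, differing in whether the vapor pressure is subtracted; they
#' differ by about 2% for micrometre nuclei in water.
#'
#' `"with_vapor"` (default):
#' `P_B = p0 - pv + (8 sigma / 9) sqrt(3 sigma / (2 (p0 - pv + 2 sigma/R0) R0^3))`.
#' `"no_vapor"` drops `pv` from both occurrences.
#'
#' @param R0 Rest radius (m), positive (vectorised).
#' @param med A [medium()].
#' @param variant `"with_vapor"` or `"no_vapor"`.
#' @return Threshold pressure (Pa). Strictly decreasing in `R0` and
#'   increasing in surface tension; tends to the static term as
#'   `R0 -> Inf`.
#' @export
#' @examples
#' blake_threshold(10e-6, medium_preset("water")$medium) / 1e3  # ~101 kPa
blake_threshold <- function(R0, med, variant = c("with_vapor", "no_vapor")) {
  variant <- match.arg(variant)
  stopifnot(all(R0 > 0))
  p0 <- med$static_pressure
  pv <- if (variant == "with_vapor") med$vapor_pressure else 0
  s <- med$surface_tension
  (p0 - pv) + (8 * s / 9) * sqrt(3 * s / (2 * (p0 - pv + 2 * s / R0) * R0^3))
}

#' Blake threshold of a bubble cluster
#'
#' The cluster's quasi-static threshold is set by its most easily activated
#' nucleus: the largest populated size class (larger nuclei have lower
#' Blake thresholds).
#'
#' @param pop A [bubble_population()].
#' @param med A [medium()].
#' @param variant Passed to [blake_threshold()].
#' @return Threshold pressure (Pa).
#' @export
#' @examples
#' cluster_blake(default_cluster(), medium_preset("water")$medium) / 1e3
cluster_blake <- function(pop, med, variant = c("with_vapor", "no_vapor")) {
  stopifnot(inherits(pop, "cav_population"))
  populated <- pop$radii[pop$counts > 0]
  if (!length(populated)) stop("population has no bubbles in any class")
  blake_threshold(max(populated), med, match.arg(variant))
}
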