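test_that("scan plus bisection agrees with the brute-force fine scan", {
  ctl <- fast_controls(n_cycles = 20, window = c(10, 18))
  tol <- 5e3
  set.seed(3)
  cases <- list(
    list(scen = scenario("water", single_bubble(1e-6)), f = 500e3),
    list(scen = scenario("water", single_bubble(3e-6)), f = 800e3),
    list(scen = scenario("liver", single_bubble(2e-6)), f = 600e3),
    list(scen = scenario("water", same_radius_cluster(1e-6)), f = 400e3),
    list(scen = scenario("liver", same_radius_cluster(6e-6, 1e5)), f = 1e6))
  for (cs in cases) {
    th <- find_threshold(cs$scen, cs$f, "r2", ctl, p_min = 10e3,
                         p_max = 1.2e6, coarse_step = 50e3, tol = tol)
    bf <- brute_force_threshold(cs$scen, cs$f, "r2", ctl, p_min = 10e3,
                                p_max = 1.2e6, tol = tol)
    expect_false(th$above_ceiling)
    expect_lte(abs(th$threshold - bf), 2 * tol)
  }
})

test_that("the criterion fires at the threshold and not just below it", {
  ctl <- fast_controls(n_cycles = 20, window = c(10, 18))
  scen <- scenario("water", single_bubble(2e-6))
  th <- find_threshold(scen, 700e3, "r2", ctl, tol = 2e3)
  crit <- cavitation_criterion("r2")
  at <- cavithresh:::.fires(scen, acoustic_drive(th$threshold, 700e3), crit,
                            ctl)
  below <- cavithresh:::.fires(scen,
                               acoustic_drive(th$threshold - 2 * 2e3, 700e3),
                               crit, ctl)
  expect_true(at$fired)
  expect_false(below$fired)
  expect_true(length(th$cavitating_radii) >= 1)
})

test_that("amplitudes above the ceiling report rather than error", {
  scen <- scenario("water", single_bubble(1e-6))
  th <- find_threshold(scen, 500e3, "r2", fast_controls(),
                       p_min = 5e3, p_max = 20e3, coarse_step = 5e3)
  expect_true(th$above_ceiling)
  expect_true(is.na(th$threshold))
})

test_that("power-law evaluation reproduces the fitted-coefficient example", {
  # viscoelastic expansion-ratio coefficients at 5 MHz
  expect_equal(eval_power_law(7.58, 0.83, 9e4, 5e6) / 1e3, 2843,
               tolerance = 2e-3)
  # f = 0 gives exactly the constant term
  expect_identical(eval_power_law(7.58, 0.83, 9e4, 0), 9e4)
})

test_that("noiseless power-law curves are recovered to 1e-6", {
  f <- 10^seq(log10(20e3), log10(2500e3), length.out = 15)
  # the tabulated viscoelastic coefficients
  fit <- fit_power_law(data.frame(frequency = f,
                                  threshold = eval_power_law(7.58, 0.83, 9e4, f)))
  expect_equal(fit$A, 7.58, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.83, tolerance = 1e-6)
  expect_equal(fit$B, 9e4, tolerance = 1e-6)
  # random coefficient draws across the plausible exponent range
  set.seed(101)
  for (i in 1:8) {
    A <- stats::runif(1, 0.1, 300)
    alpha <- stats::runif(1, 0.5, 1.1)
    B <- stats::runif(1, 2e4, 3e5)
    fit <- fit_power_law(data.frame(frequency = f,
                                    threshold = eval_power_law(A, alpha, B, f)))
    expect_equal(fit$alpha, alpha, tolerance = 1e-6)
    expect_equal(fit$A, A, tolerance = 1e-4)
  }
})

test_that("the exponent survives 2 % multiplicative noise within 0.05", {
  set.seed(202)
  f <- 10^seq(log10(20e3), log10(2500e3), length.out = 30)
  for (i in 1:5) {
    alpha <- stats::runif(1, 0.6, 1.0)
    y <- eval_power_law(25, alpha, 8e4, f) * (1 + stats::rnorm(30, 0, 0.02))
    fit <- fit_power_law(data.frame(frequency = f, threshold = y))
    expect_lt(abs(fit$alpha - alpha), 0.05)
  }
})

test_that("power-law fit objects expose broom-style methods", {
  f <- 10^seq(4.5, 6.4, length.out = 12)
  fit <- fit_power_law(data.frame(frequency = f,
                                  threshold = eval_power_law(10, 0.9, 1e5, f)))
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$estimate[td$term == "alpha"], 0.9, tolerance = 1e-5)
  gl <- generics::glance(fit)
  expect_named(gl, c("residual.norm", "nobs", "f.min", "f.max"))
  expect_equal(predict(fit, 0), unname(coef(fit)["B"]), tolerance = 1e-5)
  expect_error(fit_power_law(data.frame(frequency = 1:3, threshold = 1:3)),
               "at least 5")
})

test_that("composition clusters place the target share correctly", {
  # Q = 1/6 recovers the uniform default cluster
  pop <- cavithresh:::.composition_cluster(6e-6, 1 / 6)
  expect_equal(pop$counts, default_cluster()$counts, tolerance = 2e-5)
  # Q6 = 62.5 % puts 2.5e5 bubbles in the 6 um class
  pop <- cavithresh:::.composition_cluster(6e-6, 0.625)
  expect_equal(pop$counts[4], 2.5e5)
  expect_equal(pop$counts[-4], rep(3e4, 5))
  # Q = 0 empties the class (equivalent to a 5-class cluster)
  pop <- cavithresh:::.composition_cluster(10e-6, 0)
  expect_equal(pop$counts[6], 0)
  expect_equal(cluster_geometry(pop)$coupling_strength[6], 0)
  expect_error(cavithresh:::.composition_cluster(2e-6, 0.5),
               "default classes")
})

test_that("decoupling limit: sparse same-radius cluster meets the single bubble", {
  ctl <- fast_controls(n_cycles = 20, window = c(10, 18))
  f <- 500e3
  th_single <- find_threshold(scenario("water", single_bubble(1e-6)), f,
                              "r2", ctl, coarse_step = 20e3, tol = 2e3)
  th_sparse <- find_threshold(scenario("water", same_radius_cluster(1e-6, 10)),
                              f, "r2", ctl, coarse_step = 20e3, tol = 2e3)
  expect_lt(abs(th_single$threshold - th_sparse$threshold),
            2 * 2e3 + 0.02 * th_single$threshold)
})

test_that("threshold curves serialize to CSV and back", {
  curve <- structure(
    tibble::tibble(frequency = c(1e5, 5e5), threshold = c(1.1e5, 2.3e5),
                   criterion = "r2",
                   cavitating_radii = list(c(6e-6, 1e-5), 3e-6),
                   above_ceiling = FALSE, inconclusive = FALSE),
    class = c("cav_threshold_curve", "tbl_df", "tbl", "data.frame"))
  path <- file.path(tempdir(), "curve.csv")
  write_threshold_csv(curve, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  back <- read_threshold_csv(path)
  expect_named(back, c("f_Hz", "p_thresh_Pa", "criterion",
                       "cavitating_radii_um"))
  expect_equal(back$p_thresh_Pa, curve$threshold, tolerance = 1e-8)
  expect_identical(back$cavitating_radii_um[1], "6;10")
})

test_that("parameter-study drivers return well-formed tables", {
  ctl <- fast_controls(n_cycles = 10, window = c(5, 9))
  # composition study over two frequencies and both media
  cs <- composition_study(6e-6, 1 / 6, c(300e3, 600e3), "r2",
                          controls = ctl, coarse_step = 50e3, tol = 10e3)
  expect_s3_class(cs, "cav_threshold_curve")
  expect_setequal(cs$medium, c("water", "liver"))
  expect_equal(nrow(cs), 4)
  expect_true(all(is.finite(cs$threshold)))

  # (G, mu) map on a 2x2 grid for a decoupled bubble
  vm <- viscoelastic_map(single_bubble(6e-6), c(0, 200e3), c(9e-3, 20e-3),
                         800e3, "r2", controls = ctl,
                         coarse_step = 50e3, tol = 10e3)
  expect_equal(nrow(vm), 4)
  expect_true(all(is.finite(vm$threshold)))
  # viscosity raises the threshold along the G = 0 column
  col <- vm[vm$shear_modulus == 0, ]
  expect_gte(col$threshold[col$viscosity == 20e-3],
             col$threshold[col$viscosity == 9e-3])

  # number study on a small grid
  ns <- number_study(c(1e4, 1e5), 500e3, "r2", model = "same_radius",
                     radius = 1e-6, controls = ctl,
                     coarse_step = 50e3, tol = 10e3)
  expect_equal(ns$total_number, c(1e4, 1e5))
  expect_true(all(is.finite(ns$threshold)))
  expect_error(number_study(1e4, 500e3, model = "same_radius"),
               "radius")
})

test_that("autoplot methods return ggplot objects", {
  traj <- run_simulation(scenario("water", single_bubble(2e-6)),
                         acoustic_drive(50e3, 500e3),
                         fast_controls(n_cycles = 5, window = c(2, 4)))
  expect_s3_class(ggplot2::autoplot(traj), "ggplot")

  curve <- structure(
    tibble::tibble(frequency = c(1e5, 5e5, 1e6),
                   threshold = c(1e5, 2e5, 4e5), criterion = "r2",
                   cavitating_radii = list(1e-6, 1e-6, 1e-6),
                   above_ceiling = FALSE, inconclusive = FALSE),
    class = c("cav_threshold_curve", "tbl_df", "tbl", "data.frame"))
  expect_s3_class(ggplot2::autoplot(curve), "ggplot")

  f <- 10^seq(4.5, 6.4, length.out = 8)
  fit <- fit_power_law(data.frame(frequency = f,
                                  threshold = eval_power_law(5, 0.8, 1e5, f)))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")

  map <- structure(
    tibble::tibble(shear_modulus = c(0, 0, 1e5, 1e5),
                   viscosity = c(1e-3, 2e-3, 1e-3, 2e-3),
                   threshold = c(1, 2, 3, 4) * 1e5, above_ceiling = FALSE),
    class = c("cav_parameter_map", "tbl_df", "tbl", "data.frame"))
  expect_s3_class(ggplot2::autoplot(map), "ggplot")
})
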