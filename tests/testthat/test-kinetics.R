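# Exponential and linear kinetic fits to body-fraction time courses.

make_series <- function(model, A, tau, c, t) {
  tibble::tibble(time_min = t,
                 mean_fraction = switch(model,
                   formation = A * (1 - exp(-t / tau)) + c,
                   dissociation = A * exp(-t / tau) + c))
}

t_form <- c(0, 5, 10, 15, 20, 30, 45, 60)
t_diss <- c(0, 10, 20, 30, 45, 60, 90, 120, 180)

test_that("replicate means and sds follow the sample formulas", {
  tc <- tibble::tibble(replicate = 1:3, time_min = 0, n_cells = 10,
                       n_with_bodies = c(5, 5, 5))
  s <- mean_fraction_series(tc)
  expect_equal(s$mean_fraction, 0.5)
  expect_equal(s$sd_fraction, 0)
  tc2 <- tibble::tibble(replicate = 1:3, time_min = 0, n_cells = 10,
                        n_with_bodies = c(4, 5, 6))
  s2 <- mean_fraction_series(tc2)
  expect_equal(s2$mean_fraction, 0.5)
  expect_equal(s2$sd_fraction, 0.1)
  one <- mean_fraction_series(tc[1, ])
  expect_equal(one$mean_fraction, 0.5)
  expect_true(is.na(one$sd_fraction))
})

test_that("mismatched replicate grids are rejected", {
  tc <- tibble::tibble(replicate = c(1, 1, 2, 2),
                       time_min = c(0, 10, 0, 12),
                       n_cells = 10, n_with_bodies = 1)
  expect_error(mean_fraction_series(tc), class = "punctakit_grid_error")
})

test_that("noiseless formation data is recovered to numerical precision", {
  s <- make_series("formation", 0.49, 11, 0.08, t_form)
  fit <- fit_formation(s)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(unname(est[c("A", "tau", "c")]), c(0.49, 11, 0.08),
               tolerance = 1e-6)
  expect_lt(fit$rss, 1e-8)
})

test_that("noiseless dissociation data is recovered, with f(0) = A + c", {
  s <- make_series("dissociation", 0.5, 48, 0.05, t_diss)
  fit <- fit_dissociation(s)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(unname(est[c("A", "tau", "c")]), c(0.5, 48, 0.05),
               tolerance = 1e-6)
  expect_equal(predict(fit, 0), unname(est["A"] + est["c"]),
               tolerance = 1e-12)
  expect_lt(fit$rss, 1e-8)
})

test_that("a constant series flags tau as unidentifiable", {
  s <- tibble::tibble(time_min = t_form, mean_fraction = 0.086)
  fit <- fit_formation(s)
  expect_false(fit$tau_identifiable)
  expect_lt(fit$estimates$estimate[fit$estimates$term == "A"], 1e-6)
})

test_that("flat fits are ordinary least squares lines", {
  s <- tibble::tibble(time_min = t_form, mean_fraction = 0.086)
  fit <- fit_flat(s)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(unname(est["slope"]), 0, tolerance = 1e-12)
  expect_equal(unname(est["intercept"]), 0.086, tolerance = 1e-12)
  two <- fit_flat(tibble::tibble(time_min = c(0, 10),
                                 mean_fraction = c(0, 0.1)))
  est2 <- setNames(two$estimates$estimate, two$estimates$term)
  expect_equal(unname(est2["slope"]), 0.01)
  expect_equal(unname(est2["intercept"]), 0)
  expect_error(fit_flat(tibble::tibble(time_min = 0, mean_fraction = 0.1)),
               class = "punctakit_parameter_error")
})

test_that("scaling time by k scales the fitted tau by k exactly", {
  s <- make_series("formation", 0.4, 12, 0.05, t_form)
  s2 <- dplyr::mutate(s, time_min = time_min * 3)
  tau1 <- tidy(fit_formation(s))$estimate[2]
  tau2 <- tidy(fit_formation(s2))$estimate[2]
  expect_equal(tau2, 3 * tau1, tolerance = 1e-6)
})

test_that("mirrored formation data gives the same tau under dissociation", {
  A <- 0.45; cc <- 0.07; tau <- 14
  s <- make_series("formation", A, tau, cc, t_form)
  mirrored <- dplyr::mutate(s, mean_fraction = A + 2 * cc - mean_fraction)
  tau_d <- tidy(fit_dissociation(mirrored))$estimate[2]
  expect_equal(tau_d, tau, tolerance = 1e-6)
})

test_that("stochastic formation fits recover tau and calibrate their se", {
  res <- vapply(1:60, function(i) {
    tc <- simulate_timecourse("formation", A = 0.49, tau = 11, c = 0.08,
                              seed = 1000 + i)
    fit <- fit_formation(tc)
    est <- setNames(fit$estimates$estimate, fit$estimates$term)
    se <- setNames(fit$estimates$std_error, fit$estimates$term)
    c(est[["tau"]], se[["tau"]])
  }, numeric(2))
  expect_lt(abs(median(res[1, ]) - 11) / 11, 0.10)
  expect_gte(mean(abs(res[1, ] - 11) <= 3 * res[2, ]), 0.95)
})

test_that("fit failure carries a structured error", {
  s <- tibble::tibble(time_min = c(0, 1, 2), mean_fraction = c(0, 0.5, 1))
  expect_error(fit_formation(s), class = "punctakit_parameter_error")
})

test_that("tidy, glance, augment and autoplot cover the fit surface", {
  tc <- simulate_timecourse("formation", seed = 41)
  fit <- fit_body_kinetics(tc, "formation")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error"))
  expect_equal(glance(fit)$n_points, 8)
  aug <- augment(fit)
  expect_equal(aug$.fitted + aug$.resid, aug$mean_fraction)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the optional F-test favours the exponential on kinetic data", {
  s <- make_series("formation", 0.49, 11, 0.08, t_form)
  cmp <- compare_to_flat(fit_formation(s), fit_flat(s))
  expect_lt(cmp$p_value, 1e-6)
})
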