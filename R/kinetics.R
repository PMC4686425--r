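#' Per-timepoint mean and standard deviation of body-positive fractions
#'
#' Collapses replicate time courses to the series that gets fitted and
#' plotted: the arithmetic mean fraction at each timepoint with the
#' sample (n - 1) standard deviation across replicates. With a single
#' replicate the sd is reported as `NA`.
#'
#' @param data A time-course tibble with columns `replicate`, `time_min`,
#'   `n_cells`, `n_with_bodies` (as produced by [simulate_timecourse()]
#'   or read from a scoring sheet).
#' @return A tibble with columns `time_min`, `mean_fraction`,
#'   `sd_fraction`, `n_replicates`.
#' @export
mean_fraction_series <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("replicate", "time_min", "n_cells", "n_with_bodies") %in%
                  names(data)))
  if (any(data$n_with_bodies > data$n_cells) || any(data$n_with_bodies < 0))
    param_error("`n_with_bodies` must lie in [0, n_cells].")
  grids <- data |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(grid = paste(signif(.data$time_min, 12), collapse = ","),
                     .groups = "drop")
  if (dplyr::n_distinct(grids$grid) > 1L)
    abort("Replicates do not share a common timepoint grid.",
          class = "punctakit_grid_error")
  data |>
    dplyr::mutate(fraction = .data$n_with_bodies / .data$n_cells) |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction),
      sd_fraction = if (dplyr::n() > 1L) stats::sd(.data$fraction) else
        NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(.data$time_min)
}

#' Fit exponential or linear kinetics to a body-fraction time course
#'
#' Fits the mean body-positive fraction against time with one of the
#' three models used for scored starvation/repletion experiments:
#'
#' * `formation`: `f(t) = A * (1 - exp(-t / tau)) + c`
#' * `dissociation`: `f(t) = A * exp(-t / tau) + c`
#' * `flat`: `f(t) = intercept + slope * t` (ordinary least squares)
#'
#' The exponential fits are unweighted nonlinear least squares on the
#' replicate-mean fractions, with box constraints `A, c` in `[0, 1]` and
#' `tau` in `(0, 10 * max(t)]`, started from a small multi-start grid of
#' `tau` values (`max(t)/10`, `max(t)/3`, `max(t)`) with `A` and `c`
#' initialized from the endpoint fractions; the best converged start by
#' residual sum of squares is kept. Standard errors come from the local
#' covariance of the fit. Model choice is caller-declared per condition
#' (the flat model is for conditions where body levels do not change);
#' [compare_to_flat()] offers an F-test but is never applied
#' automatically.
#'
#' @param data Either a replicate-level time-course tibble (see
#'   [mean_fraction_series()], applied internally) or an already
#'   collapsed series with columns `time_min` and `mean_fraction`.
#' @param model `"formation"`, `"dissociation"`, or `"flat"`.
#' @param weights `"none"` (default: unweighted, the figure-level
#'   convention) or `"binomial"` to weight points by inverse binomial
#'   variance of the mean fraction (requires `n_cells`).
#' @return An object of class `kinetic_fit` with [tidy()], [glance()],
#'   [augment()][generics::augment()] and [ggplot2::autoplot()] methods.
#'   For exponential models the fields include `A`, `tau`, `c`, their
#'   standard errors, the residual sum of squares, and
#'   `tau_identifiable` (`FALSE` when the fitted amplitude is
#'   numerically zero, e.g. on a constant series, so `tau` means
#'   nothing).
#' @examples
#' tc <- simulate_timecourse("formation", A = 0.49, tau = 11, c = 0.08,
#'                           seed = 7)
#' fit <- fit_body_kinetics(tc, "formation")
#' tidy(fit)
#' @export
fit_body_kinetics <- function(data,
                              model = c("formation", "dissociation", "flat"),
                              weights = c("none", "binomial")) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  series <- as_series(data)
  if (model == "flat") return(fit_flat_series(series, data))

  t <- series$time_min
  y <- series$mean_fraction
  if (length(t) < 4L)
    param_error("Exponential fits need at least 4 timepoints.")
  if (length(unique(t)) < 4L)
    param_error("Timepoints are degenerate.")

  w <- if (weights == "binomial") binomial_weights(data, series) else
    rep(1, length(t))

  t_max <- max(t)
  form <- if (model == "formation") {
    mean_fraction ~ A * (1 - exp(-time_min / tau)) + c
  } else {
    mean_fraction ~ A * exp(-time_min / tau) + c
  }
  y_first <- y[which.min(t)]
  y_last <- y[which.max(t)]
  starts <- purrr::map(c(t_max / 10, t_max / 3, t_max), function(tau0) {
    if (model == "formation") {
      list(A = clamp01(y_last - y_first, lo = 0.01), tau = tau0,
           c = clamp01(y_first))
    } else {
      list(A = clamp01(y_first - y_last, lo = 0.01), tau = tau0,
           c = clamp01(y_last))
    }
  })

  fits <- purrr::map(starts, function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        form, data = series, start = st, weights = w,
        lower = c(A = 0, tau = 1e-6, c = 0),
        upper = c(A = 1, tau = 10 * t_max, c = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  })
  ok <- !purrr::map_lgl(fits, inherits, "error")
  if (!any(ok)) {
    abort(paste0("Exponential fit failed to converge from every start. ",
                 "Last optimizer message: ",
                 conditionMessage(fits[[length(fits)]])),
          class = "punctakit_fit_error")
  }
  rss <- purrr::map_dbl(fits, function(f)
    if (inherits(f, "error")) Inf else sum(stats::resid(f)^2))
  best <- fits[[which.min(rss)]]

  est <- coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  new_kinetic_fit(
    model = model,
    estimates = tibble(
      term = c("A", "tau", "c"),
      estimate = unname(est[c("A", "tau", "c")]),
      std_error = unname(se[c("A", "tau", "c")])),
    rss = sum(stats::resid(best)^2),
    n_points = length(t),
    series = series,
    fit = best,
    tau_identifiable = unname(est["A"]) > 1e-6)
}

#' @rdname fit_body_kinetics
#' @export
fit_formation <- function(data, weights = c("none", "binomial"))
  fit_body_kinetics(data, "formation", weights)

#' @rdname fit_body_kinetics
#' @export
fit_dissociation <- function(data, weights = c("none", "binomial"))
  fit_body_kinetics(data, "dissociation", weights)

#' @rdname fit_body_kinetics
#' @export
fit_flat <- function(data) fit_body_kinetics(data, "flat")

as_series <- function(data) {
  if (all(c("time_min", "mean_fraction") %in% names(data))) {
    as_tibble(data[order(data$time_min), ])
  } else {
    mean_fraction_series(data)
  }
}

clamp01 <- function(x, lo = 0, hi = 1) min(max(x, lo), hi)

binomial_weights <- function(data, series) {
  if (!all(c("n_cells", "replicate") %in% names(data)))
    param_error("Binomial weighting needs replicate-level counts.")
  per_t <- data |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(n_eff = sum(.data$n_cells), .groups = "drop") |>
    dplyr::arrange(.data$time_min)
  p <- pmin(pmax(series$mean_fraction, 1e-3), 1 - 1e-3)
  per_t$n_eff / (p * (1 - p))
}

fit_flat_series <- function(series, data) {
  if (nrow(series) < 2L)
    param_error("A line fit needs at least 2 timepoints.")
  fit <- lm(mean_fraction ~ time_min, data = series)
  # noiseless series fit a line exactly; the "essentially perfect fit"
  # warning from summary.lm is expected, not a defect
  se <- withCallingHandlers(
    sqrt(diag(vcov(fit))),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  new_kinetic_fit(
    model = "flat",
    estimates = tibble(
      term = c("intercept", "slope"),
      estimate = unname(coef(fit)[c("(Intercept)", "time_min")]),
      std_error = unname(se[c("(Intercept)", "time_min")])),
    rss = sum(stats::resid(fit)^2),
    n_points = nrow(series),
    series = series,
    fit = fit,
    tau_identifiable = NA)
}

new_kinetic_fit <- function(model, estimates, rss, n_points, series, fit,
                            tau_identifiable) {
  structure(list(model = model, estimates = estimates, rss = rss,
                 n_points = n_points, series = series, fit = fit,
                 tau_identifiable = tau_identifiable),
            class = "kinetic_fit")
}

#' Predicted body fraction from a kinetic fit
#'
#' @param object A `kinetic_fit`.
#' @param time_min Times (minutes) at which to evaluate the fitted curve;
#'   defaults to the fitted timepoints.
#' @param ... Unused.
#' @return Numeric vector of predicted fractions.
#' @export
predict.kinetic_fit <- function(object, time_min = NULL, ...) {
  t <- time_min %||% object$series$time_min
  p <- setNames(object$estimates$estimate, object$estimates$term)
  switch(object$model,
    formation = p[["A"]] * (1 - exp(-t / p[["tau"]])) + p[["c"]],
    dissociation = p[["A"]] * exp(-t / p[["tau"]]) + p[["c"]],
    flat = p[["intercept"]] + p[["slope"]] * t)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit: %s> %d timepoints, rss = %.3g\n",
              x$model, x$n_points, x$rss))
  print(x$estimates)
  if (isFALSE(x$tau_identifiable))
    cat("note: amplitude ~ 0; tau is not identifiable on this series\n")
  invisible(x)
}

#' @describeIn fit_body_kinetics One row per parameter (`term`,
#'   `estimate`, `std_error`).
#' @param x,object A `kinetic_fit`.
#' @param ... Unused.
#' @export
tidy.kinetic_fit <- function(x, ...) x$estimates

#' @describeIn fit_body_kinetics One-row fit summary (`model`, `rss`,
#'   `n_points`, `tau_identifiable`).
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, n_points = x$n_points,
         tau_identifiable = x$tau_identifiable)
}

#' @describeIn fit_body_kinetics The fitted series with `.fitted` and
#'   `.resid` columns.
#' @export
augment.kinetic_fit <- function(x, ...) {
  dplyr::mutate(x$series, .fitted = predict(x),
                .resid = .data$mean_fraction - .data$.fitted)
}

#' Plot a kinetic fit over the observed series
#'
#' Observed mean fractions (with sd error bars when present) and the
#' fitted curve evaluated on a fine time grid.
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  s <- object$series
  grid <- tibble(time_min = seq(min(s$time_min), max(s$time_min),
                                length.out = 200))
  grid$fit <- predict(object, grid$time_min)
  gg <- ggplot2::ggplot(s, ggplot2::aes(x = .data$time_min,
                                        y = .data$mean_fraction)) +
    ggplot2::geom_point(colour = "navy")
  if ("sd_fraction" %in% names(s) && any(is.finite(s$sd_fraction))) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sd_fraction,
                   ymax = .data$mean_fraction + .data$sd_fraction),
      width = 0, colour = "navy", na.rm = TRUE)
  }
  gg +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$time_min, y = .data$fit),
                       colour = "firebrick") +
    ggplot2::labs(x = "Time (min)", y = "Fraction of cells with bodies") +
    ggplot2::theme_minimal()
}

#' F-test comparison of an exponential fit against a flat line
#'
#' An optional aid for choosing between the exponential and flat models;
#' the package never applies it automatically — model choice is declared
#' per condition by the analyst.
#'
#' @param exp_fit A `kinetic_fit` with model `"formation"` or
#'   `"dissociation"`.
#' @param flat_fit A `kinetic_fit` with model `"flat"` on the same
#'   series.
#' @return One-row tibble with the F statistic, degrees of freedom and
#'   p-value for the exponential model's improvement over the line.
#' @export
compare_to_flat <- function(exp_fit, flat_fit) {
  stopifnot(inherits(exp_fit, "kinetic_fit"),
            inherits(flat_fit, "kinetic_fit"),
            flat_fit$model == "flat", exp_fit$model != "flat")
  n <- exp_fit$n_points
  df1 <- 1L  # 3 exponential parameters vs 2 line parameters
  df2 <- n - 3L
  if (df2 < 1L) param_error("Too few points for an F comparison.")
  f <- ((flat_fit$rss - exp_fit$rss) / df1) / (exp_fit$rss / df2)
  tibble(f_statistic = f, df1 = df1, df2 = df2,
         p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}
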