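#' Simulate a body-formation time course
#'
#' Draws per-timepoint counts of body-positive cells from the binomial
#' sampling model behind scored microscopy time courses. The expected
#' body-positive fraction follows one of three models:
#'
#' * `formation`: `p(t) = A * (1 - exp(-t / tau)) + c` (starvation),
#' * `dissociation`: `p(t) = A * exp(-t / tau) + c` (nutrient repletion),
#' * `flat`: `p(t) = c` (no change, e.g. rich medium).
#'
#' `A` is the fraction of cells that form (or lose) bodies during the
#' time course, `tau` the apparent time constant in minutes, and `c` the
#' baseline fraction with bodies at the start (formation) or end
#' (dissociation). At each timepoint, each replicate scores
#' `n_cells_per_timepoint` cells and the body-positive count is a
#' Binomial draw with success probability `p(t)`.
#'
#' Defaults mirror a typical scored experiment: three independent
#' replicates of 200 cells per timepoint over the first hour of
#' starvation. Replicates use independent seed substreams, so adding a
#' replicate leaves earlier replicates unchanged.
#'
#' @param model One of `"formation"`, `"dissociation"`, `"flat"`.
#' @param A Amplitude, fraction in `[0, 1]`. Ignored for `"flat"`.
#' @param tau Apparent time constant, minutes (> 0). Ignored for `"flat"`.
#' @param c Baseline fraction in `[0, 1]`; `A + c <= 1`.
#' @param timepoints Sampling times in minutes, non-negative, strictly
#'   increasing. The default grid spans 0-60 min for formation/flat and
#'   0-180 min for dissociation (slower decay needs a longer window).
#' @param n_cells_per_timepoint Cells inspected per timepoint per
#'   replicate.
#' @param n_replicates Number of independent replicates.
#' @param condition,strain Metadata labels carried into the output.
#' @param seed Integer seed or `NULL`.
#'
#' @return A tibble with columns `condition`, `strain`, `replicate`,
#'   `time_min`, `n_cells`, `n_with_bodies` and `fraction`, carrying the
#'   true parameters in the `"truth"` attribute.
#' @examples
#' tc <- simulate_timecourse("formation", A = 0.49, tau = 11, c = 0.08,
#'                           seed = 1)
#' mean_fraction_series(tc)
#' @export
simulate_timecourse <- function(model = c("formation", "dissociation", "flat"),
                                A = 0.49,
                                tau = 11,
                                c = 0.08,
                                timepoints = NULL,
                                n_cells_per_timepoint = 200L,
                                n_replicates = 3L,
                                condition = model,
                                strain = "wt",
                                seed = NULL) {
  model <- match.arg(model)
  check_fraction(c, "c")
  if (model != "flat") {
    check_fraction(A, "A")
    if (A + c > 1 + 1e-12)
      param_error("`A + c` must not exceed 1: p(t) would leave [0, 1].")
    if (!is.numeric(tau) || tau <= 0)
      param_error("`tau` must be a positive number of minutes.")
  }
  if (is.null(timepoints)) {
    timepoints <- if (model == "dissociation") {
      c(0, 10, 20, 30, 45, 60, 90, 120, 180)
    } else {
      c(0, 5, 10, 15, 20, 30, 45, 60)
    }
  }
  if (any(timepoints < 0) || is.unsorted(timepoints, strictly = TRUE))
    param_error("`timepoints` must be non-negative and strictly increasing.")
  n_cells_per_timepoint <- check_count(n_cells_per_timepoint,
                                       "n_cells_per_timepoint")
  n_replicates <- check_count(n_replicates, "n_replicates")

  p <- body_fraction_model(model, timepoints, A, tau, c)
  condition <- as.character(condition)[1]

  rows <- purrr::map(seq_len(n_replicates), function(r) {
    counts <- with_substream(seed, r,
      rbinom(length(timepoints), n_cells_per_timepoint, p))
    tibble(condition = condition, strain = strain, replicate = r,
           time_min = timepoints,
           n_cells = n_cells_per_timepoint,
           n_with_bodies = counts,
           fraction = counts / n_cells_per_timepoint)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(model = model,
                             A = if (model == "flat") NA_real_ else A,
                             tau = if (model == "flat") NA_real_ else tau,
                             c = c, p = p, timepoints = timepoints,
                             seed = seed)
  out
}

# Expected body-positive fraction under each kinetic model.
body_fraction_model <- function(model, t, A, tau, c) {
  switch(model,
    formation = A * (1 - exp(-t / tau)) + c,
    dissociation = A * exp(-t / tau) + c,
    flat = rep(c, length(t)),
    param_error(sprintf("Unknown kinetic model '%s'.", model))
  )
}
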