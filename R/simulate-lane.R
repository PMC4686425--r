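#' Simulate a two-band gel lane profile
#'
#' Renders a 1-D densitometry trace for one SDS-PAGE lane containing a
#' slower-migrating (phosphorylated) band near the top of the gel and a
#' faster (unphosphorylated) band below it. Pixel index 0 is the top of
#' the gel, i.e. the slowest migration. The two bands are Gaussian in
#' shape; a known fraction `phospho_fraction` of the total signal sits in
#' the top band, which is the ground truth the band-shift scorer is later
#' asked to recover.
#'
#' Noise is additive Gaussian truncated at zero (intensities cannot go
#' negative). With `noise_sd = 0` the profile integrates to
#' `total_signal` up to the (negligible, for bands several sigma away
#' from the edges) tail mass outside the lane.
#'
#' @param phospho_fraction Fraction of total signal in the shifted
#'   (phosphorylated) band, in `[0, 1]`.
#' @param n_pixels Length of the migration axis in pixels.
#' @param band_top_center,band_bottom_center Pixel positions (0-based) of
#'   the phosphorylated and unphosphorylated band centers;
#'   `band_top_center < band_bottom_center`.
#' @param band_sigma Gaussian band width in pixels.
#' @param total_signal Total lane signal in arbitrary intensity units.
#' @param noise_sd Standard deviation of the additive noise, same units.
#' @param lane_id Label carried into the output.
#' @param seed Integer seed; identical arguments and seed give a bitwise
#'   identical lane. `NULL` uses the ambient RNG.
#'
#' @return A tibble with columns `lane_id`, `position` (0-based pixel)
#'   and `intensity`, carrying the simulation ground truth in the
#'   `"truth"` attribute (a list with the true parameters).
#' @examples
#' lane <- simulate_lane(0.5, seed = 1)
#' sum(lane$intensity)
#' @export
simulate_lane <- function(phospho_fraction,
                          n_pixels = 200L,
                          band_top_center = 60,
                          band_bottom_center = 140,
                          band_sigma = 8,
                          total_signal = 1000,
                          noise_sd = 0,
                          lane_id = "lane1",
                          seed = NULL) {
  check_fraction(phospho_fraction, "phospho_fraction")
  n_pixels <- check_count(n_pixels, "n_pixels", min = 2L)
  if (band_top_center < 0 || band_bottom_center >= n_pixels)
    param_error("Band centers must lie within [0, n_pixels).")
  if (band_top_center >= band_bottom_center)
    param_error(paste("`band_top_center` must be above (smaller index than)",
                      "`band_bottom_center`: the phosphorylated species",
                      "migrates more slowly."))
  if (band_sigma <= 0) param_error("`band_sigma` must be positive.")
  if (noise_sd < 0) param_error("`noise_sd` must be non-negative.")

  pos <- seq_len(n_pixels) - 1L
  shape <- phospho_fraction * dnorm(pos, band_top_center, band_sigma) +
    (1 - phospho_fraction) * dnorm(pos, band_bottom_center, band_sigma)
  signal <- total_signal * shape
  intensity <- if (noise_sd > 0) {
    noise <- with_substream(seed, 1L, rnorm(n_pixels, 0, noise_sd))
    pmax(signal + noise, 0)
  } else {
    signal
  }

  out <- tibble(lane_id = lane_id, position = pos, intensity = intensity)
  attr(out, "truth") <- list(
    phospho_fraction = phospho_fraction,
    band_top_center = band_top_center,
    band_bottom_center = band_bottom_center,
    band_sigma = band_sigma,
    total_signal = total_signal,
    noise_sd = noise_sd,
    seed = seed
  )
  out
}

#' Simulate a batch of gel lanes with known phosphorylated fractions
#'
#' Convenience wrapper around [simulate_lane()] producing one long tibble
#' ready for [score_bandshift_batch()]. Each lane gets its own seed
#' substream, so adding lanes to a batch never changes earlier lanes.
#'
#' @param lanes A data frame with one row per lane: columns `lane_id` and
#'   `phospho_fraction`; any further columns are passed through.
#' @inheritParams simulate_lane
#' @param seed One integer seed for the whole batch.
#' @return A long tibble (`lane_id`, `position`, `intensity`) with the
#'   per-lane truth table in the `"truth"` attribute.
#' @examples
#' batch <- simulate_lane_batch(
#'   tibble::tibble(lane_id = c("wt_0min", "wt_60min"),
#'                  phospho_fraction = c(1, 0)),
#'   seed = 1)
#' @export
simulate_lane_batch <- function(lanes,
                                n_pixels = 200L,
                                band_top_center = 60,
                                band_bottom_center = 140,
                                band_sigma = 8,
                                total_signal = 1000,
                                noise_sd = 0,
                                seed = NULL) {
  stopifnot(is.data.frame(lanes),
            all(c("lane_id", "phospho_fraction") %in% names(lanes)))
  if (anyDuplicated(lanes$lane_id))
    param_error("`lane_id` values must be unique within a batch.")
  profiles <- purrr::map2(lanes$lane_id, seq_len(nrow(lanes)), function(id, i) {
    simulate_lane(lanes$phospho_fraction[i],
                  n_pixels = n_pixels,
                  band_top_center = band_top_center,
                  band_bottom_center = band_bottom_center,
                  band_sigma = band_sigma,
                  total_signal = total_signal,
                  noise_sd = noise_sd,
                  lane_id = id,
                  seed = if (is.null(seed)) NULL else substream_seed(seed, i))
  })
  out <- dplyr::bind_rows(profiles)
  attr(out, "truth") <- as_tibble(lanes)
  out
}

#' Render a 1-D lane profile into a 2-D gel-lane image
#'
#' Replicates a lane trace across a lane width and adds independent
#' pixel noise, producing the kind of image strip from which
#' [extract_lane_profile()] recovers the trace by width-averaging.
#'
#' @param profile A lane profile tibble (`position`, `intensity`).
#' @param width Lane width in pixels.
#' @param pixel_noise_sd Per-pixel additive noise (truncated at zero).
#' @param seed Integer seed or `NULL`.
#' @return A numeric matrix with `nrow(profile)` rows (migration axis)
#'   and `width` columns.
#' @export
render_lane_image <- function(profile, width = 10L, pixel_noise_sd = 0,
                              seed = NULL) {
  width <- check_count(width, "width")
  img <- matrix(rep(profile$intensity, width), ncol = width)
  if (pixel_noise_sd > 0) {
    img <- img + with_substream(seed, 1L,
      matrix(rnorm(length(img), 0, pixel_noise_sd), nrow = nrow(img)))
    img <- pmax(img, 0)
  }
  img
}
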