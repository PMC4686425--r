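#' Extract a 1-D lane profile from a 2-D gel-lane image
#'
#' Collapses a gel-lane image strip to a densitometry trace by averaging
#' signal across the lane width at each position along the migration
#' axis. Row/column 1 of the image must be the top of the gel (slowest
#' migration); the returned `position` is 0-based with 0 = top.
#'
#' @param lane_image Numeric matrix of non-negative intensities.
#' @param migration_axis `1` if rows run down the gel (default), `2` if
#'   columns do.
#' @param lane_id Label carried into the output.
#' @return A lane-profile tibble (`lane_id`, `position`, `intensity`).
#' @examples
#' extract_lane_profile(rbind(c(2, 2), c(0, 0), c(4, 4)))
#' @export
extract_lane_profile <- function(lane_image, migration_axis = 1L,
                                 lane_id = "lane1") {
  if (!is.matrix(lane_image) || !is.numeric(lane_image))
    param_error("`lane_image` must be a numeric matrix.")
  if (!migration_axis %in% c(1L, 2L))
    param_error("`migration_axis` must be 1 (rows) or 2 (columns).")
  if (dim(lane_image)[migration_axis] < 2L)
    param_error("Need at least 2 positions along the migration axis.")
  if (all(lane_image == 0))
    abort("Lane image is all zero: empty lane.",
          class = "punctakit_empty_lane_error")
  prof <- if (migration_axis == 1L) rowMeans(lane_image)
          else colMeans(lane_image)
  tibble(lane_id = lane_id, position = seq_along(prof) - 1L,
         intensity = as.numeric(prof))
}

#' Rescale a lane profile so its total signal matches a reference lane
#'
#' Lane loading varies; before position-weighted scoring, each lane is
#' scaled so its summed intensity equals that of a designated reference
#' (typically the t = 0 control of the same gel).
#'
#' @param profile,reference Lane-profile tibbles with an `intensity`
#'   column; totals must be positive.
#' @return `profile` with `intensity` scaled by
#'   `sum(reference$intensity) / sum(profile$intensity)`.
#' @export
normalize_total <- function(profile, reference) {
  tot <- sum(profile$intensity)
  ref <- sum(reference$intensity)
  if (!is.finite(tot) || tot <= 0)
    param_error("Profile total signal must be positive.")
  if (!is.finite(ref) || ref <= 0)
    param_error("Reference total signal must be positive.")
  dplyr::mutate(profile, intensity = .data$intensity * ref / tot)
}

# Linear position weights: weight_top at index 0 down to weight_bottom at
# the last index, inclusive at both ends.
position_weights <- function(n, weight_top = 100, weight_bottom = 0) {
  if (n < 2L) param_error("Profiles must have at least 2 positions.")
  weight_top + (weight_bottom - weight_top) * (seq_len(n) - 1L) / (n - 1L)
}

#' Position-weighted phosphorylation score of a lane profile
#'
#' The mobility-shift score: each position along the gel is weighted on a
#' linear scale from `weight_top` (default 100, "fully phosphorylated")
#' at the first pixel to `weight_bottom` (default 0, "unphosphorylated")
#' at the last pixel, and the weighted intensities are summed. Signal
#' sitting higher in the gel (slower migration, more phosphorylated)
#' therefore raises the score.
#'
#' The raw score is in weight units times the lane's total intensity;
#' lanes are comparable after [normalize_total()], and interpretable on
#' an absolute scale after [fit_anchor_transform()].
#'
#' @param profile Lane-profile tibble (`position`, `intensity`).
#' @param weight_top,weight_bottom Weights at the first and last pixel;
#'   must differ.
#' @return A single numeric raw score.
#' @examples
#' p <- tibble::tibble(position = 0:4, intensity = c(1, 0, 0, 0, 0))
#' position_weighted_score(p)  # 100: all signal at the top
#' @export
position_weighted_score <- function(profile, weight_top = 100,
                                    weight_bottom = 0) {
  if (weight_top == weight_bottom)
    param_error("`weight_top` and `weight_bottom` must differ.")
  I <- profile$intensity
  if (length(I) < 2L || any(I < 0) || all(I == 0))
    param_error("Profile must have >= 2 non-negative values, not all zero.")
  sum(position_weights(length(I), weight_top, weight_bottom) * I)
}

#' Two-anchor affine normalization of raw band-shift scores
#'
#' Solves for the scale (`A`) and offset (`B`) of the affine map
#' `normalized = A * raw + B` that sends the raw score of a designated
#' high anchor (wild type in rich medium, 2% glucose) to 1.0 and of a low
#' anchor (wild type fully starved, 0% glucose, 60 min) to 0.0. The same
#' constants are applied to every lane in the batch — including error
#' bars, which scale by `A`.
#'
#' @param raw_ref_high,raw_ref_low Raw scores of the two anchor lanes;
#'   must differ.
#' @return An object of class `anchor_transform`: list with `scale` and
#'   `offset`.
#' @examples
#' at <- fit_anchor_transform(80, 20)
#' at$scale * 80 + at$offset  # 1
#' @export
fit_anchor_transform <- function(raw_ref_high, raw_ref_low) {
  if (!is.finite(raw_ref_high) || !is.finite(raw_ref_low) ||
      raw_ref_high == raw_ref_low)
    abort("Anchor raw scores must be finite and distinct.",
          class = "punctakit_degenerate_anchor_error")
  structure(list(scale = 1 / (raw_ref_high - raw_ref_low),
                 offset = -raw_ref_low / (raw_ref_high - raw_ref_low),
                 raw_ref_high = raw_ref_high,
                 raw_ref_low = raw_ref_low),
            class = "anchor_transform")
}

#' @export
print.anchor_transform <- function(x, ...) {
  cat(sprintf("<anchor_transform> normalized = %.6g * raw + %.6g\n",
              x$scale, x$offset))
  invisible(x)
}

#' Predict normalized scores from an anchor transform
#'
#' @param object An `anchor_transform`.
#' @param raw Numeric vector of raw scores.
#' @param ... Unused.
#' @return Numeric vector of normalized scores (not clamped to `[0, 1]`;
#'   drift outside the anchors is reported as-is). Evaluated as
#'   `(raw - raw_ref_low) / (raw_ref_high - raw_ref_low)` — algebraically
#'   `scale * raw + offset`, but exact (0.0 and 1.0 to the last bit) at
#'   the two anchors.
#' @export
predict.anchor_transform <- function(object, raw, ...) {
  if (!is.null(object$raw_ref_low)) {
    (raw - object$raw_ref_low) / (object$raw_ref_high - object$raw_ref_low)
  } else {
    object$scale * raw + object$offset
  }
}

#' Score a batch of gel lanes with anchored normalization
#'
#' The full band-shift pipeline for one gel: every lane is total-signal
#' normalized to the reference lane, scored with the position-weighted
#' sum, and the raw scores are affinely rescaled so the designated high
#' anchor (wild type, 2% glucose) reads exactly 1.0 and the low anchor
#' (wild type, 0% glucose) exactly 0.0.
#'
#' @param profiles Long tibble of lane profiles: columns `lane_id`,
#'   `position`, `intensity`.
#' @param anchor_high_id,anchor_low_id Lane ids of the two anchors.
#' @param reference_id Lane id for total-signal normalization; defaults
#'   to the high anchor (the t = 0 control).
#' @param weight_top,weight_bottom Passed to
#'   [position_weighted_score()].
#' @param subtract_background If `TRUE`, each lane's minimum pixel value
#'   is subtracted before total normalization (off by default; the
#'   literal scoring procedure uses raw intensities).
#' @return A tibble with one row per lane: `lane_id`, `raw`,
#'   `normalized`, with the fitted [fit_anchor_transform()] in the
#'   `"anchor_transform"` attribute.
#' @examples
#' batch <- simulate_lane_batch(
#'   tibble::tibble(lane_id = c("hi", "mid", "lo"),
#'                  phospho_fraction = c(1, 0.5, 0)), seed = 1)
#' score_bandshift_batch(batch, "hi", "lo")
#' @export
score_bandshift_batch <- function(profiles,
                                  anchor_high_id,
                                  anchor_low_id,
                                  reference_id = anchor_high_id,
                                  weight_top = 100,
                                  weight_bottom = 0,
                                  subtract_background = FALSE) {
  stopifnot(is.data.frame(profiles),
            all(c("lane_id", "position", "intensity") %in% names(profiles)))
  ids <- unique(profiles$lane_id)
  missing_ids <- setdiff(c(anchor_high_id, anchor_low_id, reference_id), ids)
  if (length(missing_ids))
    abort(paste0("Anchor/reference lane(s) not in batch: ",
                 paste(missing_ids, collapse = ", ")),
          class = "punctakit_configuration_error")

  lanes <- profiles |>
    dplyr::arrange(factor(.data$lane_id, levels = ids), .data$position) |>
    dplyr::group_by(.data$lane_id) |>
    dplyr::group_split()
  names(lanes) <- purrr::map_chr(lanes, ~ .x$lane_id[1])

  if (subtract_background) {
    lanes <- purrr::map(lanes, function(p)
      dplyr::mutate(p, intensity = .data$intensity - min(.data$intensity)))
  }

  reference <- lanes[[reference_id]]
  raw <- purrr::map_dbl(lanes, function(p)
    position_weighted_score(normalize_total(p, reference),
                            weight_top, weight_bottom))

  at <- fit_anchor_transform(raw[[anchor_high_id]], raw[[anchor_low_id]])
  out <- tibble(lane_id = names(raw), raw = unname(raw),
                normalized = predict(at, unname(raw)))
  attr(out, "anchor_transform") <- at
  out
}

#' Band-shift score plot
#'
#' Bar chart of normalized band-shift scores per lane, with the two
#' anchor levels (1.0 and 0.0) marked.
#'
#' @param scores Output of [score_bandshift_batch()].
#' @return A ggplot object.
#' @export
plot_bandshift_scores <- function(scores) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$lane_id, y = .data$normalized)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "Normalized phosphorylation score") +
    ggplot2::theme_minimal()
}
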