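#' Maximum-intensity projection of one channel of a z-stack
#'
#' @param stack A `cell_stack_sim`, a 4-D `(channel, z, y, x)` array
#'   with named channels, or a 3-D `(z, y, x)` array.
#' @param channel Channel name (or index) for 4-D input; ignored for 3-D.
#' @return A `(y, x)` numeric matrix: the per-pixel maximum over z.
#' @examples
#' arr <- array(runif(2 * 4 * 4), dim = c(2, 4, 4))
#' max_project(arr)
#' @export
max_project <- function(stack, channel = "foci") {
  arr <- stack_channel(stack, channel)
  d <- dim(arr)
  planes <- lapply(seq_len(d[1]), function(z) arr[z, , , drop = TRUE])
  proj <- Reduce(pmax, planes)
  matrix(proj, nrow = d[2], ncol = d[3])
}

stack_channel <- function(stack, channel) {
  if (inherits(stack, "cell_stack_sim")) stack <- stack$stack
  nd <- length(dim(stack))
  if (nd == 3L) return(stack)
  if (nd != 4L) param_error("`stack` must be a 3-D or 4-D array.")
  chans <- dimnames(stack)[[1]]
  if (is.character(channel)) {
    if (is.null(chans) || !channel %in% chans)
      abort(sprintf("Unknown channel '%s'.", channel),
            class = "punctakit_channel_error")
  } else if (channel < 1 || channel > dim(stack)[1]) {
    abort("Channel index out of range.", class = "punctakit_channel_error")
  }
  out <- stack[channel, , , , drop = FALSE]
  array(out, dim = dim(stack)[-1])
}

# Separable Gaussian smoothing with edge replication. Kernel truncated at
# +-4 sigma; sigma = 0 returns the input untouched.
gaussian_smooth <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    # replicate-pad rows, convolve columns of the padded matrix
    padded <- m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), ,
                drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# 8-connected component labeling by iterative flood fill. Written in
# package code because the available labelers are 4-connected; intended
# for sparse foreground masks (thresholded spots), where it is linear in
# the number of foreground pixels.
label_components_8 <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  current <- 0L
  fg <- which(mask)
  for (p in fg) {
    if (labels[p] != 0L) next
    current <- current + 1L
    queue <- p
    labels[p] <- current
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      y <- ((q - 1L) %% ny) + 1L
      x <- ((q - 1L) %/% ny) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy < 1L || yy > ny || xx < 1L || xx > nx) next
        idx <- (xx - 1L) * ny + yy
        if (mask[idx] && labels[idx] == 0L) {
          labels[idx] <- current
          queue <- c(queue, idx)
        }
      }
    }
  }
  labels
}

#' Detect punctate foci on a 2-D projection
#'
#' An explicit automated stand-in for by-eye focus scoring: the
#' projection is Gaussian-smoothed, thresholded at the background median
#' plus `threshold_k` times the median absolute deviation (MAD), and
#' 8-connected components within an area band are kept as focus calls.
#' Centroids are intensity-weighted means over the smoothed component.
#'
#' On noiseless images the MAD is zero; the threshold then falls back to
#' halfway between the median and the maximum, which cleanly segments
#' isolated spots on a dark background. A flat image yields no calls.
#'
#' @param projection `(y, x)` numeric matrix, e.g. from [max_project()].
#' @param smoothing_sigma Gaussian smoothing sigma in pixels.
#' @param threshold_k MAD multiplier above the background median.
#' @param min_area,max_area Component area band, pixels.
#' @return A tibble of focus calls: `focus_id`, `y`, `x` (centroid,
#'   pixel-center coordinates), `area`, `peak_intensity` (maximum of the
#'   raw projection over the component).
#' @export
detect_foci <- function(projection, smoothing_sigma = 1, threshold_k = 5,
                        min_area = 4L, max_area = 200L) {
  stopifnot(is.matrix(projection), is.numeric(projection))
  if (length(projection) == 0) param_error("Empty projection.")
  sm <- gaussian_smooth(projection, smoothing_sigma)
  med <- median(sm)
  dev <- mad(sm)
  # a MAD that is zero (or negligible against the dynamic range, as on
  # noiseless renders) cannot anchor a noise threshold; fall back to
  # halfway between background median and maximum
  thr <- if (dev > 1e-6 * (max(sm) - med)) med + threshold_k * dev
         else med + 0.5 * (max(sm) - med)
  mask <- sm > thr
  empty <- tibble(focus_id = integer(), y = numeric(), x = numeric(),
                  area = integer(), peak_intensity = numeric())
  if (!any(mask)) return(empty)
  labels <- label_components_8(mask)
  comp_ids <- seq_len(max(labels))
  rows <- purrr::map(comp_ids, function(cid) {
    idx <- which(labels == cid)
    area <- length(idx)
    if (area < min_area || area > max_area) return(NULL)
    ny <- nrow(projection)
    ys <- ((idx - 1L) %% ny) + 1L
    xs <- ((idx - 1L) %/% ny) + 1L
    w <- sm[idx]
    tibble(y = sum(w * (ys - 0.5)) / sum(w),
           x = sum(w * (xs - 0.5)) / sum(w),
           area = area,
           peak_intensity = max(projection[idx]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  dplyr::mutate(out, focus_id = dplyr::row_number(), .before = 1)
}

#' Assign detected foci to cells and tally per-cell body counts
#'
#' Each focus is assigned to the cell label under its centroid in a
#' labeled cell map (0 = background). Foci landing on background are
#' dropped and counted in the `"n_background_foci"` attribute. Every
#' labeled cell gets a record, including cells with zero bodies.
#'
#' @param foci Focus-call tibble from [detect_foci()].
#' @param cell_map Integer matrix of cell labels, same shape as the
#'   projection.
#' @return A tibble with one row per labeled cell: `cell_id`,
#'   `n_bodies`, `has_body`.
#' @export
assign_to_cells <- function(foci, cell_map) {
  stopifnot(is.matrix(cell_map))
  cells <- sort(unique(cell_map[cell_map > 0]))
  counts <- setNames(integer(length(cells)), cells)
  dropped <- 0L
  for (i in seq_len(nrow(foci))) {
    yy <- min(max(ceiling(foci$y[i]), 1L), nrow(cell_map))
    xx <- min(max(ceiling(foci$x[i]), 1L), ncol(cell_map))
    lab <- cell_map[yy, xx]
    if (lab > 0) counts[as.character(lab)] <- counts[as.character(lab)] + 1L
    else dropped <- dropped + 1L
  }
  out <- tibble(cell_id = as.integer(cells), n_bodies = unname(counts),
                has_body = unname(counts) >= 1L)
  attr(out, "n_background_foci") <- dropped
  out
}

#' Fraction of cells carrying at least one body
#'
#' Point estimate with a Wilson score 95% confidence interval.
#'
#' @param records Per-cell tibble with a logical `has_body` column, e.g.
#'   from [assign_to_cells()].
#' @param conf_level Confidence level for the score interval.
#' @return One-row tibble: `n_cells`, `n_with_bodies`, `fraction`,
#'   `conf_low`, `conf_high`.
#' @examples
#' body_fraction(tibble::tibble(has_body = rep(c(TRUE, FALSE), c(57, 43))))
#' @export
body_fraction <- function(records, conf_level = 0.95) {
  stopifnot(is.data.frame(records), "has_body" %in% names(records))
  n <- nrow(records)
  if (n == 0) param_error("Need at least one cell record.")
  k <- sum(records$has_body)
  ci <- wilson_interval(k, n, conf_level)
  tibble(n_cells = n, n_with_bodies = k, fraction = k / n,
         conf_low = ci[1], conf_high = ci[2])
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(k, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Two-channel co-localization fraction
#'
#' Among cells possessing at least one channel-A focus, the fraction in
#' which some A focus lies within `distance_px` of a channel-B focus of
#' the same cell. No default distance is claimed; it is a required
#' analysis choice.
#'
#' @param foci_a,foci_b Focus-call tibbles for the two channels
#'   ([detect_foci()] output).
#' @param cell_map Labeled cell map used to group foci by cell.
#' @param distance_px Centroid distance threshold in pixels.
#' @return One-row tibble: `n_eligible` (cells with >= 1 A focus),
#'   `n_colocalized`, `fraction`.
#' @export
colocalization_fraction <- function(foci_a, foci_b, cell_map, distance_px) {
  if (missing(distance_px) || !is.numeric(distance_px) || distance_px <= 0)
    param_error("`distance_px` is required and must be positive.")
  label_at <- function(f) {
    purrr::map_int(seq_len(nrow(f)), function(i) {
      yy <- min(max(ceiling(f$y[i]), 1L), nrow(cell_map))
      xx <- min(max(ceiling(f$x[i]), 1L), ncol(cell_map))
      as.integer(cell_map[yy, xx])
    })
  }
  ca <- if (nrow(foci_a)) label_at(foci_a) else integer()
  cb <- if (nrow(foci_b)) label_at(foci_b) else integer()
  eligible <- setdiff(unique(ca), 0L)
  if (!length(eligible))
    return(tibble(n_eligible = 0L, n_colocalized = 0L, fraction = NA_real_))
  colocalized <- purrr::map_lgl(eligible, function(cell) {
    a <- foci_a[ca == cell, ]
    b <- foci_b[cb == cell, ]
    if (nrow(b) == 0) return(FALSE)
    d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
      sqrt((a$y[i] - b$y[j])^2 + (a$x[i] - b$x[j])^2))
    any(d <= distance_px)
  })
  tibble(n_eligible = length(eligible),
         n_colocalized = sum(colocalized),
         fraction = mean(colocalized))
}

#' Count bodies per cell in a stack, end to end
#'
#' Convenience pipeline: project the focus channel, detect foci, assign
#' them to cells. Works directly on a [simulate_cell_stack()] object
#' (using its bundled cell map) or on a raw array plus a map.
#'
#' @param stack A `cell_stack_sim` or a `(channel, z, y, x)` array.
#' @param cell_map Labeled cell map; taken from the simulation object if
#'   omitted.
#' @param channel Focus channel name.
#' @inheritParams detect_foci
#' @return The per-cell tibble of [assign_to_cells()].
#' @export
count_bodies <- function(stack, cell_map = NULL, channel = "foci",
                         smoothing_sigma = 1, threshold_k = 5,
                         min_area = 4L, max_area = 200L) {
  if (is.null(cell_map)) {
    if (!inherits(stack, "cell_stack_sim"))
      param_error("`cell_map` is required for raw arrays.")
    cell_map <- stack$cell_map
  }
  proj <- max_project(stack, channel)
  foci <- detect_foci(proj, smoothing_sigma, threshold_k, min_area, max_area)
  assign_to_cells(foci, cell_map)
}

#' Histogram of bodies per cell
#'
#' @param records Per-cell tibble (`n_bodies` column).
#' @return A ggplot object: frequency distribution of per-cell body
#'   counts.
#' @export
plot_body_count_histogram <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$n_bodies)) +
    ggplot2::geom_bar(fill = "goldenrod") +
    ggplot2::labs(x = "Bodies per cell", y = "Cells") +
    ggplot2::theme_minimal()
}

#' Read and write image stacks as multi-page TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2,
#' ...), with the channel names and dimensions recorded in a YAML
#' sidecar written next to the TIFF.
#'
#' @param stack 4-D `(channel, z, y, x)` array with named channels.
#' @param path Output TIFF path; the sidecar is `<path>.yaml`.
#' @return `path`, invisibly (writer); the 4-D array (reader).
#' @export
write_stack_tiff <- function(stack, path) {
  if (inherits(stack, "cell_stack_sim")) stack <- stack$stack
  d <- dim(stack)
  chans <- dimnames(stack)[[1]]
  hi <- max(stack)
  scale <- if (hi > 0) hi else 1
  pages <- list()
  for (ch in seq_len(d[1])) for (z in seq_len(d[2]))
    pages[[length(pages) + 1L]] <-
      matrix(stack[ch, z, , ] / scale, d[3], d[4])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(channels = as.list(chans), n_z = d[2],
                        intensity_scale = scale,
                        page_order = "channel-major"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  chans <- unlist(meta$channels)
  n_z <- meta$n_z
  d <- dim(pages[[1]])
  stack <- array(0, dim = c(length(chans), n_z, d[1], d[2]),
                 dimnames = list(channel = chans, NULL, NULL, NULL))
  i <- 1L
  for (ch in seq_along(chans)) for (z in seq_len(n_z)) {
    stack[ch, z, , ] <- pages[[i]] * meta$intensity_scale
    i <- i + 1L
  }
  stack
}
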