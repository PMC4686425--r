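#' Simulate a two-channel 3-D image stack of cells with fluorescent foci
#'
#' Renders a field of cells, each drawn as a membrane ring (the vacuolar
#' membrane marker) in one channel and, with probability
#' `body_probability`, one or more punctate bodies in the focus channel.
#' Foci are 3-D Gaussian spots planted in an annulus just outside the
#' membrane ring — at the vacuolar edge, where the agglomerates of
#' interest sit. With probability `colocalization_probability` a focus is
#' additionally planted at (essentially) the same site in a third,
#' `marker` channel, emulating a second tagged protein that may or may
#' not co-localize.
#'
#' Cells are laid out on a regular grid of square tiles; the labeled cell
#' map (disk of radius `membrane_ring_radius + 5` per cell) is returned
#' alongside, since segmentation is out of scope for the analysis module.
#' Foci that would fall outside the image, or closer than `min_separation`
#' to a sibling focus in projection, are re-drawn — never silently
#' clipped. All randomness is per-cell substreamed, so growing `n_cells`
#' leaves earlier cells' draws unchanged.
#'
#' @param n_cells Number of cells to render.
#' @param body_probability Chance a cell carries at least one focus.
#' @param bodies_per_cell_weights Named weights over focus counts
#'   `{1, 2, 3}` for body-positive cells. The default puts 90% of mass on
#'   a single body per cell, the dominant observed mode.
#' @param n_z Number of z-planes (default 5, at nominal 1 um spacing).
#' @param focus_intensity Peak focus intensity above background.
#' @param focus_sigma Lateral Gaussian radius of a focus, pixels.
#' @param membrane_ring_radius Ring radius, pixels.
#' @param membrane_intensity Peak ring intensity.
#' @param background_sd Additive Gaussian background noise sd (truncated
#'   at zero); 0 gives noiseless images.
#' @param colocalization_probability Chance a focus is mirrored in the
#'   `marker` channel.
#' @param min_separation Minimum projected distance between foci of the
#'   same cell, pixels.
#' @param seed Integer seed or `NULL`.
#'
#' @return An object of class `cell_stack_sim`: a list with
#'   * `stack`: numeric array `(channel, z, y, x)` with channels
#'     `foci`, `marker`, `membrane`;
#'   * `cell_map`: integer matrix `(y, x)` of cell labels (0 background);
#'   * `cells`: tibble of per-cell truth (`cell_id`, `center_y`,
#'     `center_x`, `n_bodies`, `has_body`, `colocalized`);
#'   * `foci`: tibble of every planted focus (`cell_id`, `channel`, `z`,
#'     `y`, `x`).
#' @examples
#' sim <- simulate_cell_stack(25, body_probability = 0.6, seed = 1)
#' mean(sim$cells$has_body)
#' @export
simulate_cell_stack <- function(n_cells,
                                body_probability = 0.57,
                                bodies_per_cell_weights = c(`1` = 0.9,
                                                            `2` = 0.08,
                                                            `3` = 0.02),
                                n_z = 5L,
                                focus_intensity = 120,
                                focus_sigma = 1.2,
                                membrane_ring_radius = 6,
                                membrane_intensity = 60,
                                background_sd = 8,
                                colocalization_probability = 0,
                                min_separation = 7,
                                seed = NULL) {
  n_cells <- check_count(n_cells, "n_cells")
  check_fraction(body_probability, "body_probability")
  check_fraction(colocalization_probability, "colocalization_probability")
  n_z <- check_count(n_z, "n_z")
  if (background_sd < 0) param_error("`background_sd` must be non-negative.")
  k_vals <- as.integer(names(bodies_per_cell_weights))
  if (any(is.na(k_vals)) || any(k_vals < 1))
    param_error("`bodies_per_cell_weights` must be named by positive counts.")

  tile <- 2L * ceiling(membrane_ring_radius + 3 + 4 * focus_sigma + 1)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  ny <- nrow_grid * tile
  nx <- ncol_grid * tile

  channels <- c("foci", "marker", "membrane")
  stack <- array(0, dim = c(3L, n_z, ny, nx),
                 dimnames = list(channel = channels, NULL, NULL, NULL))
  cell_map <- matrix(0L, ny, nx)

  centers <- tibble(
    cell_id = seq_len(n_cells),
    center_y = ((seq_len(n_cells) - 1L) %/% ncol_grid) * tile + tile / 2,
    center_x = ((seq_len(n_cells) - 1L) %% ncol_grid) * tile + tile / 2
  )

  foci_rows <- list()
  has_body <- logical(n_cells)
  n_bodies <- integer(n_cells)
  colocalized <- logical(n_cells)

  half <- tile / 2
  local_y <- seq_len(tile) - 0.5  # pixel centers within a tile
  ring_tile <- outer(local_y - half, local_y - half,
                     function(dy, dx) {
                       r <- sqrt(dy^2 + dx^2)
                       membrane_intensity * exp(-(r - membrane_ring_radius)^2 /
                                                  (2 * 0.8^2))
                     })
  disk_tile <- outer(local_y - half, local_y - half,
                     function(dy, dx)
                       sqrt(dy^2 + dx^2) <= membrane_ring_radius + 5)

  for (i in seq_len(n_cells)) {
    y0 <- (centers$center_y[i] - half)
    x0 <- (centers$center_x[i] - half)
    ys <- (y0 + 1):(y0 + tile)
    xs <- (x0 + 1):(x0 + tile)
    cell_map[ys, xs][disk_tile] <- i
    for (z in seq_len(n_z))
      stack["membrane", z, ys, xs] <- stack["membrane", z, ys, xs] + ring_tile

    draws <- with_substream(seed, i, {
      body <- runif(1) < body_probability
      k <- if (body) {
        sample(k_vals, 1, prob = bodies_per_cell_weights)
      } else 0L
      # rejection-sample annulus positions with pairwise separation
      pts <- matrix(numeric(0), ncol = 2)
      tries <- 0L
      while (nrow(pts) < k && tries < 200L) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, membrane_ring_radius + 1, membrane_ring_radius + 3)
        cand <- c(centers$center_y[i] + rad * sin(ang),
                  centers$center_x[i] + rad * cos(ang))
        ok <- nrow(pts) == 0 ||
          all(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2,
                                         byrow = TRUE))^2)) >= min_separation)
        if (ok) pts <- rbind(pts, cand)
        tries <- tries + 1L
      }
      if (nrow(pts) < k) {
        # deterministic fallback: equally spaced angles
        ang <- 2 * pi * (seq_len(k) - 1) / k
        rad <- membrane_ring_radius + 2
        pts <- cbind(centers$center_y[i] + rad * sin(ang),
                     centers$center_x[i] + rad * cos(ang))
      }
      zc <- if (k > 0) runif(k, 1.5, n_z - 0.5) else numeric(0)
      coloc <- if (k > 0) runif(k) < colocalization_probability else logical(0)
      jit <- if (k > 0) matrix(rnorm(2 * k, 0, 0.3), k, 2) else NULL
      list(k = k, pts = pts, zc = zc, coloc = coloc, jit = jit)
    })

    n_bodies[i] <- draws$k
    has_body[i] <- draws$k > 0
    colocalized[i] <- any(draws$coloc)
    for (j in seq_len(draws$k)) {
      fy <- draws$pts[j, 1]; fx <- draws$pts[j, 2]; fz <- draws$zc[j]
      stack <- add_gaussian_spot(stack, "foci", fz, fy, fx,
                                 focus_intensity, focus_sigma)
      foci_rows[[length(foci_rows) + 1L]] <-
        tibble(cell_id = i, channel = "foci", z = fz, y = fy, x = fx)
      if (draws$coloc[j]) {
        my <- fy + draws$jit[j, 1]; mx <- fx + draws$jit[j, 2]
        stack <- add_gaussian_spot(stack, "marker", fz, my, mx,
                                   focus_intensity, focus_sigma)
        foci_rows[[length(foci_rows) + 1L]] <-
          tibble(cell_id = i, channel = "marker", z = fz, y = my, x = mx)
      }
    }
  }

  if (background_sd > 0) {
    noise <- with_substream(seed, n_cells + 1L,
      array(rnorm(length(stack), 0, background_sd), dim = dim(stack)))
    stack <- stack + noise
    stack[stack < 0] <- 0
    dimnames(stack) <- list(channel = channels, NULL, NULL, NULL)
  }

  cells <- dplyr::mutate(centers, n_bodies = n_bodies,
                         has_body = has_body, colocalized = colocalized)
  structure(
    list(stack = stack, cell_map = cell_map, cells = cells,
         foci = if (length(foci_rows)) dplyr::bind_rows(foci_rows) else
           tibble(cell_id = integer(), channel = character(),
                  z = numeric(), y = numeric(), x = numeric())),
    class = "cell_stack_sim")
}

# Accumulate a 3-D Gaussian spot into one channel of a (c, z, y, x) array.
# Evaluated on a local cube of +-4 sigma; anything beyond is negligible.
add_gaussian_spot <- function(stack, channel, zc, yc, xc, peak, sigma,
                              sigma_z = 0.8) {
  d <- dim(stack)
  ys <- max(1, floor(yc - 4 * sigma)):min(d[3], ceiling(yc + 4 * sigma))
  xs <- max(1, floor(xc - 4 * sigma)):min(d[4], ceiling(xc + 4 * sigma))
  zs <- seq_len(d[2])
  gy <- exp(-((ys - 0.5) - yc)^2 / (2 * sigma^2))
  gx <- exp(-((xs - 0.5) - xc)^2 / (2 * sigma^2))
  gz <- exp(-((zs - 0.5) - zc)^2 / (2 * sigma_z^2))
  spot <- peak * outer(gz, outer(gy, gx))
  stack[channel, , ys, xs] <- stack[channel, , ys, xs] + spot
  stack
}

#' @export
print.cell_stack_sim <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf(
    "<cell_stack_sim> %d cells, stack %d channel(s) x %d z x %d x %d px\n",
    nrow(x$cells), d[1], d[2], d[3], d[4]))
  cat(sprintf("  body-positive: %d/%d (%.1f%%), planted foci: %d\n",
              sum(x$cells$has_body), nrow(x$cells),
              100 * mean(x$cells$has_body),
              sum(x$foci$channel == "foci")))
  invisible(x)
}
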