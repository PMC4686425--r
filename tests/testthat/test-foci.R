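# Foci counting and co-localization on maximum projections.

test_that("maximum projection matches trivial and brute-force cases", {
  one <- array(runif(16), dim = c(1, 4, 4))
  expect_equal(max_project(one), matrix(one[1, , ], 4, 4))
  two <- array(0, dim = c(2, 3, 3))
  two[2, , ] <- matrix(1:9, 3, 3)
  expect_equal(max_project(two), matrix(1:9, 3, 3))
  withr::with_seed(81, {
    for (i in 1:10) {
      arr <- array(runif(5 * 8 * 7), dim = c(5, 8, 7))
      expect_equal(max_project(arr), oracle_max_project(arr))
    }
  })
})

test_that("unknown channels are refused", {
  sim <- simulate_cell_stack(4, seed = 82)
  expect_error(max_project(sim, "nope"), class = "punctakit_channel_error")
})

test_that("blank and flat images produce no focus calls", {
  expect_identical(nrow(detect_foci(matrix(0, 30, 30))), 0L)
  expect_identical(nrow(detect_foci(matrix(7, 30, 30))), 0L)
})

test_that("a single planted spot is called once, within a pixel", {
  img <- matrix(0, 40, 40)
  for (y in 1:40) for (x in 1:40)
    img[y, x] <- 100 * exp(-((y - 0.5 - 17.3)^2 + (x - 0.5 - 24.8)^2) /
                             (2 * 1.2^2))
  calls <- detect_foci(img)
  expect_identical(nrow(calls), 1L)
  expect_lt(abs(calls$y - 17.3), 1)
  expect_lt(abs(calls$x - 24.8), 1)
})

test_that("detection is translation-equivariant away from edges", {
  base <- matrix(0, 50, 50)
  spot <- function(img, yc, xc) {
    for (y in 1:50) for (x in 1:50)
      img[y, x] <- img[y, x] +
        90 * exp(-((y - 0.5 - yc)^2 + (x - 0.5 - xc)^2) / (2 * 1.2^2))
    img
  }
  a <- detect_foci(spot(base, 20, 20))
  b <- detect_foci(spot(base, 23, 25))
  expect_identical(nrow(a), 1L)
  expect_identical(nrow(b), 1L)
  expect_lt(abs((b$y - a$y) - 3), 0.5)
  expect_lt(abs((b$x - a$x) - 5), 0.5)
})

test_that("foci are assigned to cells, background calls tallied", {
  cmap <- matrix(0L, 20, 20)
  cmap[3:8, 3:8] <- 1L
  cmap[12:18, 12:18] <- 3L
  no_foci <- tibble::tibble(focus_id = integer(), y = numeric(),
                            x = numeric(), area = integer(),
                            peak_intensity = numeric())
  rec0 <- assign_to_cells(no_foci, cmap)
  expect_identical(rec0$n_bodies, c(0L, 0L))
  one <- tibble::tibble(focus_id = 1:2, y = c(14.2, 1.5), x = c(14.9, 1.5),
                        area = 5L, peak_intensity = 50)
  rec <- assign_to_cells(one, cmap)
  expect_identical(rec$n_bodies[rec$cell_id == 3], 1L)
  expect_identical(rec$n_bodies[rec$cell_id == 1], 0L)
  expect_identical(attr(rec, "n_background_foci"), 1L)
})

test_that("body fraction uses the Wilson score interval", {
  rec <- function(k, n) tibble::tibble(has_body = rep(c(TRUE, FALSE),
                                                      c(k, n - k)))
  expect_equal(body_fraction(rec(0, 100))$fraction, 0)
  expect_equal(body_fraction(rec(100, 100))$fraction, 1)
  bf <- body_fraction(rec(57, 100))
  expect_equal(bf$fraction, 0.57)
  oracle <- stats::prop.test(57, 100, correct = FALSE)$conf.int
  expect_equal(c(bf$conf_low, bf$conf_high), as.numeric(oracle),
               tolerance = 1e-9)
  expect_error(body_fraction(rec(0, 100)[0, ]),
               class = "punctakit_parameter_error")
})

test_that("noiseless end-to-end counts equal the planted truth", {
  sim <- simulate_cell_stack(64, body_probability = 0.6,
                             background_sd = 0, seed = 83)
  rec <- count_bodies(sim)
  expect_identical(rec$n_bodies, sim$cells$n_bodies)
  expect_equal(body_fraction(rec)$fraction, mean(sim$cells$has_body))
})

test_that("co-localization fractions follow the planted contract", {
  f <- tibble::tibble(focus_id = 1:2, y = c(5, 15), x = c(5, 15),
                      area = 5L, peak_intensity = 50)
  cmap <- matrix(0L, 20, 20)
  cmap[1:10, 1:10] <- 1L
  cmap[11:20, 11:20] <- 2L
  expect_equal(colocalization_fraction(f, f, cmap, 2)$fraction, 1)
  far <- dplyr::mutate(f, y = y + 4)
  expect_equal(colocalization_fraction(f, far, cmap, 2)$fraction, 0)
  expect_error(colocalization_fraction(f, f, cmap),
               class = "punctakit_parameter_error")
})

test_that("detected co-localization matches simulator ground truth", {
  sim <- simulate_cell_stack(300, body_probability = 0.6,
                             colocalization_probability = 0.1, seed = 84)
  fa <- detect_foci(max_project(sim, "foci"))
  fb <- detect_foci(max_project(sim, "marker"))
  est <- colocalization_fraction(fa, fb, sim$cell_map, 2)
  truth <- mean(sim$cells$colocalized[sim$cells$has_body])
  expect_lt(abs(est$fraction - truth),
            3 * sqrt(0.1 * 0.9 / est$n_eligible) + 1e-9)
})

test_that("stack TIFF round trip preserves voxels to 16-bit precision", {
  sim <- simulate_cell_stack(9, seed = 85)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "stack.tif")
  write_stack_tiff(sim, path)
  back <- read_stack_tiff(path)
  expect_identical(dim(back), dim(sim$stack))
  expect_identical(dimnames(back)[[1]], dimnames(sim$stack)[[1]])
  expect_lt(max(abs(back - sim$stack)), max(sim$stack) / 65535 + 1e-9)
})
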