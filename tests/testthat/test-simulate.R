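# Synthetic-data generators: ground truth, conservation, reproducibility.

test_that("single-band limit lanes put all mass at the stated center", {
  top <- simulate_lane(1, noise_sd = 0)
  bot <- simulate_lane(0, noise_sd = 0)
  com <- function(p) sum(p$position * p$intensity) / sum(p$intensity)
  expect_equal(com(top), 60, tolerance = 1e-9)
  expect_equal(com(bot), 140, tolerance = 1e-9)
})

test_that("noiseless lane integral conserves total signal", {
  for (f in c(0, 0.3, 1)) {
    lane <- simulate_lane(f, noise_sd = 0, total_signal = 1234)
    expect_equal(sum(lane$intensity), 1234, tolerance = 1e-6 * 1234)
  }
})

test_that("equal-fraction lane splits mass symmetrically about the midpoint", {
  lane <- simulate_lane(0.5, noise_sd = 0)
  mid <- (60 + 140) / 2
  upper <- sum(lane$intensity[lane$position < mid])
  lower <- sum(lane$intensity[lane$position > mid])
  expect_equal(upper, lower, tolerance = 1e-9 * upper)
})

test_that("lane simulation rejects invalid fractions and geometry", {
  expect_error(simulate_lane(1.2), class = "punctakit_parameter_error")
  expect_error(simulate_lane(0.5, band_top_center = 150,
                             band_bottom_center = 60),
               class = "punctakit_parameter_error")
  expect_error(simulate_lane(0.5, band_bottom_center = 400),
               class = "punctakit_parameter_error")
})

test_that("lane batches are seed-reproducible and substream-stable", {
  lanes2 <- tibble::tibble(lane_id = c("l1", "l2"),
                           phospho_fraction = c(0.8, 0.2))
  lanes3 <- dplyr::bind_rows(lanes2,
    tibble::tibble(lane_id = "l3", phospho_fraction = 0.5))
  a <- simulate_lane_batch(lanes2, noise_sd = 4, seed = 11)
  b <- simulate_lane_batch(lanes2, noise_sd = 4, seed = 11)
  expect_identical(a$intensity, b$intensity)
  c3 <- simulate_lane_batch(lanes3, noise_sd = 4, seed = 11)
  expect_identical(c3$intensity[c3$lane_id %in% c("l1", "l2")], a$intensity)
})

test_that("flat time course at zero baseline yields zero counts", {
  tc <- simulate_timecourse("flat", c = 0, seed = 1)
  expect_true(all(tc$n_with_bodies == 0))
})

test_that("formation model starts exactly at the baseline fraction", {
  tc <- simulate_timecourse("formation", A = 0.4, c = 0.1, tau = 9, seed = 2)
  truth <- attr(tc, "truth")
  expect_identical(truth$p[truth$timepoints == 0], 0.1)
})

test_that("empirical fractions track the kinetic model within binomial error", {
  tc <- simulate_timecourse("formation", A = 0.49, tau = 11, c = 0.08,
                            n_cells_per_timepoint = 10000, n_replicates = 1,
                            seed = 3)
  truth <- attr(tc, "truth")
  p <- truth$p
  expect_true(all(abs(tc$fraction - p) <= 3 * sqrt(p * (1 - p) / 10000)))
})

test_that("time-course simulation rejects probabilities above one", {
  expect_error(simulate_timecourse("formation", A = 0.8, c = 0.4, tau = 5),
               class = "punctakit_parameter_error")
  expect_error(simulate_timecourse("formation", timepoints = c(5, 5, 10)),
               class = "punctakit_parameter_error")
})

test_that("adding a replicate never perturbs earlier replicates", {
  a <- simulate_timecourse("formation", n_replicates = 2, seed = 4)
  b <- simulate_timecourse("formation", n_replicates = 3, seed = 4)
  expect_identical(a$n_with_bodies,
                   b$n_with_bodies[b$replicate <= 2])
})

test_that("sequences without insertions on a Q/N-free background have no Q/N", {
  sim <- simulate_sequence(50, seed = 5)
  expect_identical(qn_composition(sim, 0, 50)$qn_count, 0L)
})

test_that("planted motifs carry the rounded Q/N count", {
  sim <- simulate_sequence(100,
    motifs = tibble::tibble(position = 10, motif_length = 20,
                            qn_fraction = 1.0), seed = 6)
  expect_equal(qn_composition(sim, 10, 30)$qn_percent, 100)
  sim2 <- simulate_sequence(100,
    motifs = tibble::tibble(position = 30, motif_length = 34,
                            qn_fraction = 0.5), seed = 7)
  expect_identical(qn_composition(sim2, 30, 64)$qn_count, 17L)
})

test_that("overlapping motif insertions are rejected", {
  expect_error(simulate_sequence(100,
    motifs = tibble::tibble(position = c(10, 25),
                            motif_length = c(20, 20),
                            qn_fraction = 0.5)),
    class = "punctakit_parameter_error")
})

test_that("cell stacks honour body probability limits and emit truth", {
  none <- simulate_cell_stack(20, body_probability = 0, seed = 8)
  expect_identical(nrow(none$foci), 0L)
  all1 <- simulate_cell_stack(20, body_probability = 1,
                              bodies_per_cell_weights = c(`1` = 1), seed = 9)
  expect_identical(nrow(all1$foci), 20L)
  expect_true(all(all1$cells$n_bodies == 1L))
})

test_that("planted body-positive fraction matches the binomial design", {
  sim <- simulate_cell_stack(500, body_probability = 0.57,
                             background_sd = 0, seed = 10)
  expect_lt(abs(mean(sim$cells$has_body) - 0.57),
            3 * sqrt(0.57 * 0.43 / 500))
})

test_that("stack simulation is bitwise reproducible", {
  a <- simulate_cell_stack(16, seed = 12)
  b <- simulate_cell_stack(16, seed = 12)
  expect_identical(a$stack, b$stack)
  expect_identical(a$foci, b$foci)
})
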