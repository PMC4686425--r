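# Q/N prion-like motif quantitation and compositional scanning.

test_that("Q/N composition counts and percentages are exact", {
  expect_equal(qn_composition("QQQQQ", 0, 5)$qn_percent, 100)
  expect_identical(qn_composition("ACDEF", 0, 5)$qn_count, 0L)
  expect_equal(qn_composition("ACDEF", 0, 5)$qn_percent, 0)
  # a 78-residue interval with 28 Q/N reports 35.90% at 2 decimals
  seq78 <- paste0(strrep("Q", 28), strrep("A", 50))
  comp <- qn_composition(seq78, 0, 78)
  expect_identical(comp$qn_count, 28L)
  expect_equal(round(comp$qn_percent, 2), 35.90)
  expect_error(qn_composition("ACDEF", 0, 6),
               class = "punctakit_coordinate_error")
  expect_error(qn_composition("ACDEF", 3, 3),
               class = "punctakit_coordinate_error")
})

test_that("composition is invariant under residue permutation", {
  withr::with_seed(51, {
    chars <- c(rep("Q", 7), rep("N", 4), sample(c("A", "S", "G", "L"), 19,
                                                replace = TRUE))
    for (i in 1:10) {
      shuffled <- paste(sample(chars), collapse = "")
      expect_identical(qn_composition(shuffled, 0, 30)$qn_count, 11L)
    }
  })
})

test_that("ambiguity codes count toward length but never toward Q/N", {
  comp <- qn_composition("QXXNX", 0, 5)
  expect_identical(comp$qn_count, 2L)
  expect_equal(comp$qn_percent, 40)
})

test_that("scanning an all-Q sequence yields one full-length interval", {
  iv <- scan_qn_windows(strrep("Q", 60), window_length = 20,
                        qn_threshold = 0.4)
  expect_identical(nrow(iv), 1L)
  expect_identical(c(iv$start, iv$end), c(0L, 60L))
})

test_that("scanning a Q/N-free sequence yields nothing", {
  iv <- scan_qn_windows(strrep("ACDEFGHIKL", 10), window_length = 20,
                        qn_threshold = 0.4)
  expect_identical(nrow(iv), 0L)
})

test_that("a window longer than the sequence warns and returns empty", {
  expect_warning(iv <- scan_qn_windows("QQQQ", window_length = 20),
                 "shorter than the window")
  expect_identical(nrow(iv), 0L)
})

test_that("planted motifs are recovered with high overlap across seeds", {
  for (s in 1:100) {
    sim <- simulate_sequence(200,
      motifs = tibble::tibble(position = 80, motif_length = 40,
                              qn_fraction = 0.6), seed = s)
    iv <- scan_qn_windows(sim, window_length = 20, qn_threshold = 0.4,
                          merge_gap = 10)
    expect_identical(nrow(iv), 1L)
    expect_gte(jaccard_interval(iv$start, iv$end, 80, 120), 0.8)
  }
})

test_that("scan output intervals are disjoint, sorted and Q/N-bounded", {
  sim <- simulate_sequence(400,
    motifs = tibble::tibble(position = c(50, 250),
                            motif_length = c(40, 40),
                            qn_fraction = c(0.8, 0.7)), seed = 61)
  iv <- scan_qn_windows(sim, window_length = 20, qn_threshold = 0.4)
  expect_identical(nrow(iv), 2L)
  expect_true(all(diff(iv$start) > 0))
  expect_true(all(iv$end[-nrow(iv)] <= iv$start[-1]))
  # reported intervals begin and end on a Q/N residue
  res <- strsplit(sim$residues, "")[[1]]
  expect_true(all(res[iv$start + 1] %in% c("Q", "N")))
  expect_true(all(res[iv$end] %in% c("Q", "N")))
})

test_that("alanine replacement hits only targeted residues in range", {
  expect_identical(mutate_interval_to_alanine("AQQA", 1, 3)$residues, "AAAA")
  expect_identical(mutate_interval_to_alanine("ASGL", 0, 4)$residues, "ASGL")
  # N is preserved when only Q is targeted
  expect_identical(
    mutate_interval_to_alanine("QNQN", 0, 4, target_residues = "Q")$residues,
    "ANAN")
})

test_that("mutating a motif to alanine abolishes its Q/N signal", {
  sim <- simulate_sequence(200,
    motifs = tibble::tibble(position = 80, motif_length = 40,
                            qn_fraction = 0.6), seed = 62)
  mut <- mutate_interval_to_alanine(sim, 80, 120)
  expect_equal(qn_composition(mut, 80, 120)$qn_percent, 0)
  iv <- scan_qn_windows(mut, window_length = 20, qn_threshold = 0.4)
  expect_identical(nrow(iv), 0L)
})

test_that("composition tables match simulator ground truth exactly", {
  panel <- purrr::map(1:17, function(i) {
    simulate_sequence(300,
      motifs = tibble::tibble(position = c(40, 200),
                              motif_length = c(60, 30),
                              qn_fraction = c(0.3 + 0.02 * i, 0.5)),
      seq_id = sprintf("sp%02d", i), seed = 70 + i)
  })
  seqs <- dplyr::bind_rows(panel)
  truth <- dplyr::bind_rows(purrr::map(panel, attr, "truth"))
  intervals <- dplyr::mutate(truth,
    label = rep(c("PriLM1", "PriLM2"), 17), has_tsc = rep(c("+", "-"), 17))
  tab <- composition_table(seqs, intervals)
  expect_identical(nrow(tab), 34L)
  expect_identical(tab$qn_count, truth$qn_count)
  expect_equal(tab$qn_percent,
               round(100 * truth$qn_count / (truth$end - truth$start), 2))
  expect_identical(tab$has_tsc, intervals$has_tsc)
  # empty manifest and dangling references
  expect_identical(nrow(composition_table(seqs, intervals[0, ])), 0L)
  bad <- dplyr::mutate(intervals[1, ], seq_id = "nope")
  expect_error(composition_table(seqs, bad),
               class = "punctakit_coordinate_error")
})

test_that("FASTA and interval-manifest round trips preserve content", {
  dir <- withr::local_tempdir()
  seqs <- tibble::tibble(seq_id = c("s1", "s2"),
                         residues = c("MQQNA", "ACDEFG"))
  fa <- file.path(dir, "panel.fasta")
  write_protein_fasta(seqs, fa)
  expect_equal(as.data.frame(read_protein_fasta(fa)), as.data.frame(seqs))
  manifest <- file.path(dir, "intervals.tsv")
  readr::write_tsv(tibble::tibble(seq_id = "s1", label = "M1",
                                  start_1based = 2, end_1based = 4,
                                  note = "x"), manifest)
  iv <- read_interval_manifest(manifest)
  expect_identical(c(iv$start, iv$end), c(1L, 4L))
  expect_identical(qn_composition(seqs, iv$start, iv$end)$qn_count, 3L)
})
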