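#' Q/N composition of a sequence interval
#'
#' Counts glutamine (Q) and asparagine (N) residues in a stated interval
#' of a protein sequence and reports the count together with the
#' percentage of the interval length — the quantitation used for
#' prion-like motif (PriLM) tables. Ambiguity codes (`X`) and any
#' non-Q/N character count toward the interval length but never toward
#' the Q/N count, so percentages are conservative.
#'
#' Coordinates are 0-based half-open internally; the reader
#' [read_interval_manifest()] converts from the 1-based inclusive
#' convention used in reports.
#'
#' @param sequences A tibble with columns `seq_id` and `residues`
#'   (uppercase amino-acid strings), e.g. from [read_protein_fasta()] or
#'   [simulate_sequence()]. A single bare string is also accepted.
#' @param start,end Interval, 0-based half-open, within the sequence.
#' @param seq_id Which sequence to use when `sequences` has several
#'   rows; defaults to the first.
#' @return A one-row tibble: `seq_id`, `start`, `end`, `length`,
#'   `qn_count`, `qn_percent` (percent, stored at full precision;
#'   report tables round to 2 decimals).
#' @examples
#' qn_composition("QQNQA", 0, 5)
#' @export
qn_composition <- function(sequences, start, end, seq_id = NULL) {
  seqs <- as_sequence_tbl(sequences)
  row <- pick_sequence(seqs, seq_id)
  check_interval(start, end, nchar(row$residues), row$seq_id)
  segment <- substr(row$residues, start + 1L, end)
  qn <- qn_count(segment)
  len <- end - start
  tibble(seq_id = row$seq_id, start = as.integer(start),
         end = as.integer(end), length = as.integer(len),
         qn_count = qn, qn_percent = 100 * qn / len)
}

qn_count <- function(segment) {
  chars <- strsplit(segment, "")[[1]]
  sum(chars %in% c("Q", "N"))
}

as_sequence_tbl <- function(sequences) {
  if (is.character(sequences)) {
    ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
    sequences <- tibble(seq_id = ids, residues = unname(sequences))
  }
  stopifnot(is.data.frame(sequences),
            all(c("seq_id", "residues") %in% names(sequences)))
  out <- as_tibble(sequences)
  if (any(nchar(out$residues) == 0))
    param_error("Sequences must be non-empty.")
  dplyr::mutate(out, residues = toupper(.data$residues))
}

pick_sequence <- function(seqs, seq_id) {
  if (is.null(seq_id)) return(seqs[1, ])
  hit <- seqs[seqs$seq_id == seq_id, ]
  if (nrow(hit) == 0)
    abort(sprintf("No sequence with id '%s'.", seq_id),
          class = "punctakit_coordinate_error")
  hit[1, ]
}

check_interval <- function(start, end, seq_len, seq_id) {
  if (start < 0 || end > seq_len || start >= end)
    abort(sprintf(
      "Interval [%s, %s) is invalid for sequence '%s' of length %d.",
      format(start), format(end), seq_id, seq_len),
      class = "punctakit_coordinate_error")
  invisible(TRUE)
}

#' Scan a protein sequence for Q/N-rich intervals
#'
#' A transparent compositional stand-in for HMM-based prion-domain
#' callers: slides a window along the sequence, flags windows whose Q/N
#' fraction reaches `qn_threshold`, merges flagged windows that overlap
#' or lie within `merge_gap` residues of each other, and trims each
#' merged interval to its outermost Q/N residues. Prion-like motifs are
#' Q/N-rich almost by definition, so composition recovers planted or
#' strongly Q/N-biased motifs; it makes no claim of reproducing
#' HMM-defined boundaries.
#'
#' @inheritParams qn_composition
#' @param window_length Window size, residues.
#' @param qn_threshold Minimum Q/N fraction in a window to flag it,
#'   in `(0, 1]`.
#' @param merge_gap Flagged windows separated by up to this many
#'   residues are merged.
#' @return A tibble of disjoint, sorted intervals per sequence:
#'   `seq_id`, `start`, `end` (0-based half-open), `length`, `qn_count`,
#'   `qn_percent`. Sequences shorter than the window contribute no rows
#'   and raise a warning.
#' @examples
#' scan_qn_windows(paste0(strrep("A", 30), strrep("Q", 25),
#'                        strrep("A", 30)),
#'                 window_length = 20, qn_threshold = 0.4)
#' @export
scan_qn_windows <- function(sequences, window_length = 20L,
                            qn_threshold = 0.4, merge_gap = 10L) {
  window_length <- check_count(window_length, "window_length")
  check_fraction(qn_threshold, "qn_threshold", allow_zero = FALSE)
  merge_gap <- check_count(merge_gap, "merge_gap", min = 0L)
  seqs <- as_sequence_tbl(sequences)

  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    s <- seqs$residues[i]
    n <- nchar(s)
    if (n < window_length) {
      warn(sprintf("Sequence '%s' (length %d) is shorter than the window (%d); skipped.",
                   seqs$seq_id[i], n, window_length))
      return(tibble(seq_id = character(), start = integer(),
                    end = integer(), length = integer(),
                    qn_count = integer(), qn_percent = numeric()))
    }
    is_qn <- strsplit(s, "")[[1]] %in% c("Q", "N")
    # Q/N count in each length-`window_length` window via cumulative sums
    cs <- c(0L, cumsum(is_qn))
    win_counts <- cs[(window_length + 1L):(n + 1L)] - cs[1:(n - window_length + 1L)]
    flagged <- which(win_counts / window_length >= qn_threshold)
    if (!length(flagged)) {
      return(tibble(seq_id = character(), start = integer(),
                    end = integer(), length = integer(),
                    qn_count = integer(), qn_percent = numeric()))
    }
    starts <- flagged - 1L          # 0-based window starts
    ends <- starts + window_length  # half-open window ends
    merged <- merge_intervals(starts, ends, merge_gap)
    rows <- purrr::map_dfr(seq_len(nrow(merged)), function(j) {
      trimmed <- trim_to_qn(is_qn, merged$start[j], merged$end[j])
      if (is.null(trimmed)) return(NULL)
      qn_composition(seqs[i, ], trimmed[1], trimmed[2])
    })
    rows
  })
}

# Merge 0-based half-open intervals whose gap is <= merge_gap.
merge_intervals <- function(starts, ends, merge_gap) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me <= merge_gap) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Shrink [start, end) to the outermost Q/N residues inside it.
trim_to_qn <- function(is_qn, start, end) {
  idx <- which(is_qn[(start + 1L):end])
  if (!length(idx)) return(NULL)
  c(start + idx[1] - 1L, start + idx[length(idx)])
}

#' Mutate Q/N residues in an interval to alanine
#'
#' The in-silico counterpart of disrupting a prion-like motif by
#' mutating its glutamine stretch to alanine: residues in the interval
#' that belong to `target_residues` become `A`; everything else,
#' including interval length, is untouched.
#'
#' @inheritParams qn_composition
#' @param target_residues Subset of `c("Q", "N")` to replace.
#' @return The `sequences` tibble with the chosen sequence mutated.
#' @examples
#' mutate_interval_to_alanine("AQQA", 1, 3)$residues
#' @export
mutate_interval_to_alanine <- function(sequences, start, end,
                                       target_residues = c("Q", "N"),
                                       seq_id = NULL) {
  stopifnot(all(target_residues %in% c("Q", "N")))
  seqs <- as_sequence_tbl(sequences)
  row <- pick_sequence(seqs, seq_id)
  check_interval(start, end, nchar(row$residues), row$seq_id)
  chars <- strsplit(row$residues, "")[[1]]
  span <- (start + 1L):end
  hit <- span[chars[span] %in% target_residues]
  chars[hit] <- "A"
  seqs$residues[seqs$seq_id == row$seq_id] <- paste(chars, collapse = "")
  seqs
}

#' Q/N composition table for a panel of sequences and intervals
#'
#' Builds the per-sequence, per-motif quantitation table: one row per
#' (sequence, interval label) with Q/N counts and percentages, plus any
#' annotation columns of the interval manifest passed through untouched
#' (e.g. presence/absence of pathway genes).
#'
#' @inheritParams qn_composition
#' @param intervals A tibble with columns `seq_id`, `label`, `start`,
#'   `end` (0-based half-open; see [read_interval_manifest()]) and
#'   optional annotation columns.
#' @return A tibble with columns `seq_id`, `label`, `start`, `end`,
#'   `length`, `qn_count`, `qn_percent` (rounded to 2 decimals, the
#'   table convention) and the annotations.
#' @export
composition_table <- function(sequences, intervals) {
  seqs <- as_sequence_tbl(sequences)
  intervals <- as_tibble(intervals)
  if (nrow(intervals) == 0) {
    return(tibble(seq_id = character(), label = character(),
                  start = integer(), end = integer(), length = integer(),
                  qn_count = integer(), qn_percent = numeric()))
  }
  stopifnot(all(c("seq_id", "label", "start", "end") %in% names(intervals)))
  dangling <- setdiff(unique(intervals$seq_id), seqs$seq_id)
  if (length(dangling))
    abort(paste0("Interval manifest references missing sequence(s): ",
                 paste(dangling, collapse = ", ")),
          class = "punctakit_coordinate_error")
  extra <- setdiff(names(intervals), c("seq_id", "label", "start", "end"))
  purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    comp <- qn_composition(seqs, intervals$start[i], intervals$end[i],
                           seq_id = intervals$seq_id[i])
    out <- dplyr::mutate(comp, label = intervals$label[i],
                         qn_percent = round(.data$qn_percent, 2),
                         .after = "seq_id")
    for (col in extra) out[[col]] <- intervals[[col]][i]
    out
  })
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A tibble with columns `seq_id` (first word of the header) and
#'   `residues` (uppercase).
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble(seq_id = sub("\\s.*$", "", names(set)),
         residues = toupper(as.character(set)))
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Tibble with `seq_id` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  seqs <- as_sequence_tbl(sequences)
  set <- Biostrings::AAStringSet(setNames(seqs$residues, seqs$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an interval manifest (1-based inclusive) into internal coordinates
#'
#' Report-facing manifests use 1-based inclusive coordinates
#' (`start_1based`, `end_1based`); internally everything is 0-based
#' half-open. This reader performs the conversion.
#'
#' @param path TSV with columns `seq_id`, `label`, `start_1based`,
#'   `end_1based` plus free annotation columns.
#' @return Tibble with `seq_id`, `label`, `start`, `end` (0-based
#'   half-open) and the annotations.
#' @export
read_interval_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("seq_id", "label", "start_1based", "end_1based") %in%
                  names(m)))
  m |>
    dplyr::mutate(start = as.integer(.data$start_1based - 1L),
                  end = as.integer(.data$end_1based)) |>
    dplyr::select(-"start_1based", -"end_1based") |>
    dplyr::relocate("seq_id", "label", "start", "end")
}
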