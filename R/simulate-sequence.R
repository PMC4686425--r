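#' Simulate a protein sequence with planted Q/N-rich motifs
#'
#' Draws a background amino-acid sequence from per-residue alphabet
#' weights and plants glutamine/asparagine-rich motifs at stated
#' positions, emulating prion-like-motif-bearing proteins. Each planted
#' motif of length `L` and target Q/N fraction `f` contains exactly
#' `round(f * L)` Q/N residues (split between Q and N at random,
#' Q-biased 2:1 as in glutamine-rich yeast prion domains), shuffled with
#' non-Q/N filler at random positions within the motif.
#'
#' @param length Total sequence length in residues.
#' @param motifs A data frame with one row per planted motif: columns
#'   `position` (0-based start), `motif_length`, `qn_fraction`. `NULL` or
#'   zero rows plants nothing.
#' @param background_weights Named numeric vector of sampling weights
#'   over the 20-residue alphabet for background positions. The default
#'   weights are uniform over the 18 non-Q/N residues (a Q/N-free
#'   background, so planted motifs are the only Q/N signal).
#' @param seq_id Identifier carried into the output.
#' @param seed Integer seed or `NULL`.
#'
#' @return A one-row tibble with columns `seq_id` and `residues`, with
#'   the planted motif intervals (`start`, `end` 0-based half-open,
#'   `qn_count`) in the `"truth"` attribute.
#' @examples
#' sim <- simulate_sequence(200,
#'   motifs = tibble::tibble(position = 80, motif_length = 40,
#'                           qn_fraction = 0.6),
#'   seed = 1)
#' attr(sim, "truth")
#' @export
simulate_sequence <- function(length,
                              motifs = NULL,
                              background_weights = NULL,
                              seq_id = "seq1",
                              seed = NULL) {
  length <- check_count(length, "length")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(background_weights)) {
    background_weights <- setNames(as.numeric(!aa %in% c("Q", "N")), aa)
  }
  if (is.null(names(background_weights)) ||
      !all(names(background_weights) %in% aa))
    param_error("`background_weights` must be named by amino-acid letters.")

  motifs <- if (is.null(motifs)) {
    tibble(position = integer(), motif_length = integer(),
           qn_fraction = numeric())
  } else {
    as_tibble(motifs)
  }
  if (nrow(motifs) > 0) {
    motifs <- dplyr::arrange(motifs, .data$position)
    starts <- motifs$position
    ends <- motifs$position + motifs$motif_length
    if (any(starts < 0) || any(ends > length))
      param_error("Motif insertions must fit within the sequence.")
    if (any(motifs$qn_fraction < 0 | motifs$qn_fraction > 1))
      param_error("`qn_fraction` must lie in [0, 1].")
    if (nrow(motifs) > 1 && any(starts[-1] < ends[-nrow(motifs)]))
      param_error("Motif insertions must not overlap.")
  }

  residues <- with_substream(seed, 1L, {
    bg <- sample(names(background_weights), length, replace = TRUE,
                 prob = background_weights)
    for (i in seq_len(nrow(motifs))) {
      L <- motifs$motif_length[i]
      n_qn <- round(motifs$qn_fraction[i] * L)
      qn <- sample(c("Q", "N"), n_qn, replace = TRUE, prob = c(2, 1))
      filler_pool <- setdiff(names(background_weights)[background_weights > 0],
                             c("Q", "N"))
      if (!base::length(filler_pool)) filler_pool <- c("A", "G", "S")
      filler <- sample(filler_pool, L - n_qn, replace = TRUE)
      motif <- sample(c(qn, filler))
      bg[(motifs$position[i] + 1):(motifs$position[i] + L)] <- motif
    }
    bg
  })

  out <- tibble(seq_id = seq_id, residues = paste(residues, collapse = ""))
  attr(out, "truth") <- tibble(
    seq_id = seq_id,
    start = as.integer(motifs$position),
    end = as.integer(motifs$position + motifs$motif_length),
    qn_count = as.integer(round(motifs$qn_fraction * motifs$motif_length))
  )
  out
}
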