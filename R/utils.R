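# Internal helpers shared across modules.

# Counter-based seed substream: expanding one user seed into independent
# per-replicate / per-cell streams, so adding a replicate never perturbs
# the draws of earlier replicates. Constants are the Lehmer multiplier and
# Knuth's multiplicative hash; the result always fits a 32-bit signed int.
substream_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  x <- (abs(as.double(seed)) * 48271 + as.double(counter) * 2654435761) %%
    2147483629
  as.integer(x)
}

# Evaluate `expr` under a deterministic substream without disturbing the
# caller's RNG state. seed = NULL means "use the ambient RNG as-is".
with_substream <- function(seed, counter, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(substream_seed(seed, counter), expr)
}

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 ||
      (!allow_zero && x == 0) || (!allow_one && x == 1)) {
    abort(sprintf("`%s` must be a single number in [%s, %s], got %s.",
                  name, if (allow_zero) "0" else "0 (exclusive)",
                  if (allow_one) "1" else "1 (exclusive)",
                  deparse(substitute(x))),
          class = "punctakit_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "punctakit_parameter_error")
  }
  invisible(as.integer(x))
}

param_error <- function(msg) {
  abort(msg, class = "punctakit_parameter_error")
}

# Provenance header written atop every pipeline output file.
provenance_header <- function(seed, config_hash = NA_character_) {
  c(sprintf("# punctakit %s",
            as.character(utils::packageVersion("punctakit"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# config_hash: %s", config_hash))
}

write_tsv_with_header <- function(x, path, seed, config_hash = NA_character_) {
  hdr <- provenance_header(seed, config_hash)
  con <- file(path, open = "wb")  # binary mode: byte-identical across runs
  on.exit(close(con))
  writeLines(hdr, con)
  body <- readr::format_tsv(x)
  writeBin(charToRaw(body), con)
  invisible(path)
}

read_tsv_skip_header <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}
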