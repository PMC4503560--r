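# Internal helpers shared across modules.

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Vectorized reverse complement on plain character vectors.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

assert_counts <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must contain non-negative integer counts", name))
  }
  invisible(x)
}

# Coerce reads given as DNAStringSet, character vector, or a tibble with
# read_id/sequence columns into a tibble(read_id, sequence).
as_read_tbl <- function(reads) {
  if (is_tibble(reads) || is.data.frame(reads)) {
    if (!all(c("read_id", "sequence") %in% names(reads))) {
      abort("read data frames need `read_id` and `sequence` columns")
    }
    return(as_tibble(reads)[, c("read_id", "sequence")])
  }
  if (methods::is(reads, "DNAStringSet")) {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    return(tibble(read_id = ids, sequence = as.character(reads)))
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    return(tibble(read_id = ids, sequence = unname(reads)))
  }
  abort("unsupported read container; use a DNAStringSet, character vector or tibble")
}

# Reads from a FASTQ/FASTA file into a tibble(read_id, sequence).
read_sequencing_reads <- function(path) {
  if (!file.exists(path)) abort(sprintf("read file not found: %s", path))
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  dss <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- sub("\\s.*$", "", names(dss))
  tibble(read_id = ids, sequence = as.character(dss))
}
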