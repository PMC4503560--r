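# Genome I/O. Genomes are Biostrings::DNAStringSet objects with unique,
# non-empty scaffold names and an alphabet restricted to {A,C,G,T,N}.

GENOME_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a genome from a FASTA file
#'
#' Reads a multi-record FASTA file into a named [Biostrings::DNAStringSet].
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of each header. Records with duplicate or empty ids, empty
#' sequences, or characters outside `A,C,G,T,N` are rejected.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A named `DNAStringSet`, one entry per record in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), fa)
#' read_genome(fa)
read_genome <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", paste(path, collapse = ", ")))
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) abort(sprintf("no FASTA records in %s", path))
  ids <- sub("\\s.*$", "", names(raw))
  if (any(ids == "")) abort("FASTA record with empty id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA record id: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) {
    abort(sprintf("empty FASTA record: %s",
                  paste(ids[nchar(seqs) == 0L], collapse = ", ")))
  }
  bad <- grepl(sprintf("[^%s]", paste(GENOME_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    abort(sprintf("illegal character (outside A,C,G,T,N) in record(s): %s",
                  paste(ids[bad], collapse = ", ")))
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- ids
  genome
}

#' Write a genome to a FASTA file
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = width)
  invisible(path)
}

#' Coerce to a genome container
#'
#' Accepts a named `DNAStringSet` or named character vector and validates
#' the genome invariants (unique non-empty scaffold ids, sequences of
#' length >= 1 over `A,C,G,T,N`).
#'
#' @param x Object to coerce.
#' @return A validated named `DNAStringSet`.
#' @export
as_genome <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (!methods::is(x, "DNAStringSet")) {
    abort("a genome must be a named DNAStringSet or named character vector")
  }
  ids <- names(x)
  if (is.null(ids) || any(ids == "")) abort("all scaffolds must be named")
  if (anyDuplicated(ids)) abort("scaffold ids must be unique")
  if (any(Biostrings::width(x) == 0L)) abort("scaffold sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(x)
  extra <- freq[, setdiff(colnames(freq), GENOME_ALPHABET), drop = FALSE]
  if (any(extra > 0)) abort("genome alphabet restricted to A,C,G,T,N")
  x
}
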