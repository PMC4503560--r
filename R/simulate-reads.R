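# Synthetic DNA-seq libraries with junction-spanning reads.
#
# For each IES the number of junction-spanning fragments is Poisson with
# mean `coverage`; each fragment carries the unexcised form (drawn across
# an IES boundary on the MAC+IES haplotype) with probability r -- the true
# retention fraction -- and the excised junction (drawn across the MAC
# junction) otherwise. Conditional on the Poisson draw the IES+ count is
# exactly binomial, which is the model the retention statistics assume.

#' Construct a retention truth table
#'
#' @param annotations IES annotation tibble.
#' @param r True per-IES retention fraction in `[0, 1]`; recycled.
#' @param coverage Expected junction-spanning reads per IES per sample.
#' @return A tibble `ies_id`, `r`, `coverage`.
#' @export
retention_truth <- function(annotations, r = 0, coverage = 100) {
  if (any(r < 0 | r > 1)) abort("`r` must lie in [0, 1]")
  if (any(coverage <= 0)) abort("`coverage` must be positive")
  tibble(ies_id = annotations$ies_id, r = as.numeric(r),
         coverage = as.numeric(coverage))
}

#' Simulate junction-spanning reads for a retention truth
#'
#' Emits single-end reads of fixed length: per IES, `N ~ Poisson(coverage)`
#' junction-spanning reads, each IES+ with probability `r` (substring of
#' the MAC+IES scaffold across a randomly chosen boundary) and IES-
#' otherwise (substring of the MAC scaffold across the junction); read
#' start offsets are uniform among the offsets that leave at least
#' `overhang` bases on each side of the crossed boundary. Background reads
#' from non-junction MAC regions are added on top (`background_fraction`
#' of the final library). Each read is reverse-complemented with
#' probability 1/2; read ids encode the origin for oracle checks.
#'
#' @param mac,mac_plus_ies The two references.
#' @param annotations IES annotation tibble.
#' @param truth Truth table from [retention_truth()].
#' @param read_length Read length in nt (default 101).
#' @param overhang Minimum bases required on each side of the crossed
#'   boundary (default 5); must satisfy `read_length >= 2 * overhang + 2`.
#' @param background_fraction Fraction of the library drawn from
#'   non-junction regions (default 0.3).
#' @param substitution_rate Optional uniform per-base substitution rate
#'   (default 0, i.e. error-free).
#' @param seed Integer seed.
#' @param fastq,truth_path Optional output paths; when given, a Phred+33
#'   FASTQ (fixed quality "I") and a tab-separated truth table are written.
#' @return A list with `reads` (tibble: read_id, ies_id, type, ref,
#'   scaffold, pos, strand, sequence), `truth`, and `summary` (reads per
#'   type).
#' @export
simulate_excision_reads <- function(mac, mac_plus_ies, annotations, truth,
                                    read_length = 101L, overhang = 5L,
                                    background_fraction = 0.3,
                                    substitution_rate = 0, seed = 1L,
                                    fastq = NULL, truth_path = NULL) {
  mac <- as_genome(mac)
  mac_plus_ies <- as_genome(mac_plus_ies)
  L <- as.integer(read_length)
  k <- as.integer(overhang)
  if (L < 2L * k + 2L) {
    abort("read_length too short to span a junction with the requested overhang")
  }
  assert_scalar_number(background_fraction, "background_fraction", 0, 0.95)
  assert_scalar_number(substitution_rate, "substitution_rate", 0, 0.5)
  coords <- ies_coordinates(annotations)
  truth <- as_tibble(truth)
  if (!setequal(truth$ies_id, coords$ies_id)) {
    abort("truth table must cover exactly the annotated IESs")
  }
  coords <- left_join(coords, truth, by = "ies_id")
  mac_chr <- as.character(mac)
  gl_chr <- as.character(mac_plus_ies)

  with_seed(seed, {
    per_ies <- vector("list", nrow(coords))
    for (i in seq_len(nrow(coords))) {
      ci <- coords[i, ]
      n_total <- rpois(1L, ci$coverage)
      if (n_total == 0L) next
      n_plus <- rbinom(1L, n_total, ci$r)
      n_minus <- n_total - n_plus
      rows <- list()
      if (n_minus > 0L) {
        lo <- ci$junction_pos + 1L + k - L + 1L
        hi <- ci$junction_pos - k
        if (lo < 1L || hi + L - 1L > nchar(mac_chr[[ci$scaffold]])) {
          abort(sprintf("IES %s too close to a scaffold end for read length %d",
                        ci$ies_id, L))
        }
        start <- lo + sample.int(hi - lo + 1L, n_minus, replace = TRUE) - 1L
        rows$minus <- tibble(
          ies_id = ci$ies_id, type = "minus", ref = "mac",
          scaffold = ci$scaffold, pos = start,
          sequence = substr(rep(mac_chr[[ci$scaffold]], n_minus),
                            start, start + L - 1L)
        )
      }
      if (n_plus > 0L) {
        side <- sample(c("left", "right"), n_plus, replace = TRUE)
        # the boundary anchor is the IES's terminal TA; like the junction
        # probe, a counted read carries k bases on each side of it:
        # left window [start-k, start+k+1], right window [end-k-1, end+k]
        w_lo <- ifelse(side == "left", ci$start - k, ci$end - k - 1L)
        w_hi <- ifelse(side == "left", ci$start + k + 1L, ci$end + k)
        lo <- w_hi - L + 1L
        hi <- w_lo
        if (any(lo < 1L) || any(hi + L - 1L > nchar(gl_chr[[ci$scaffold]]))) {
          abort(sprintf("IES %s too close to a scaffold end for read length %d",
                        ci$ies_id, L))
        }
        start <- floor(runif(n_plus, min = lo, max = hi + 1L))
        rows$plus <- tibble(
          ies_id = ci$ies_id, type = "plus", ref = "mac_plus_ies",
          scaffold = ci$scaffold, pos = as.integer(start),
          sequence = substr(rep(gl_chr[[ci$scaffold]], n_plus),
                            start, start + L - 1L)
        )
      }
      per_ies[[i]] <- bind_rows(rows)
    }
    reads <- bind_rows(per_ies)
    n_junction <- nrow(reads)

    if (background_fraction > 0 && n_junction > 0L) {
      n_bg <- round(n_junction * background_fraction / (1 - background_fraction))
      reads <- bind_rows(reads,
                         simulate_background_reads(mac_chr, coords, n_bg, L, k))
    }
    if (substitution_rate > 0 && nrow(reads) > 0L) {
      reads$sequence <- mutate_bases(reads$sequence, substitution_rate)
    }
    if (nrow(reads) > 0L) {
      reads <- reads[sample.int(nrow(reads)), ]
      reads$strand <- ifelse(runif(nrow(reads)) < 0.5, "+", "-")
      flip <- reads$strand == "-"
      reads$sequence[flip] <- revcomp(reads$sequence[flip])
      reads <- mutate(
        reads,
        read_id = sprintf("sim%07d:%s:%s:%s:%d:%s", row_number(), .data$type,
                          if_else(is.na(.data$ies_id), .data$scaffold, .data$ies_id),
                          .data$ref, .data$pos, .data$strand)
      ) |>
        select("read_id", "ies_id", "type", "ref", "scaffold", "pos",
               "strand", "sequence")
    } else {
      reads <- tibble(read_id = character(), ies_id = character(),
                      type = character(), ref = character(),
                      scaffold = character(), pos = integer(),
                      strand = character(), sequence = character())
    }
    if (!is.null(fastq)) write_reads_fastq(reads, fastq)
    if (!is.null(truth_path)) {
      utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    list(reads = reads, truth = truth,
         summary = dplyr::count(reads, .data$type, name = "n_reads"))
  })
}

# Background reads drawn from MAC regions whose span does not fully cover
# any junction probe window, so they classify as NONE downstream.
simulate_background_reads <- function(mac_chr, coords, n_bg, L, k) {
  if (n_bg <= 0L) return(NULL)
  widths <- nchar(mac_chr)
  ok_scaffold <- widths >= L
  out <- list()
  got <- 0L
  guard <- 0L
  while (got < n_bg && guard < 50L) {
    guard <- guard + 1L
    m <- 2L * (n_bg - got)
    sc <- sample(names(mac_chr)[ok_scaffold], m, replace = TRUE,
                 prob = widths[ok_scaffold])
    start <- floor(runif(m, 1, widths[sc] - L + 2L))
    cand <- tibble(scaffold = sc, pos = as.integer(start))
    # reject reads that fully contain a junction probe window
    win <- coords |>
      select("scaffold", "junction_pos") |>
      mutate(w_lo = .data$junction_pos - k, w_hi = .data$junction_pos + 1L + k)
    cand <- cand |>
      left_join(win, by = "scaffold", relationship = "many-to-many") |>
      group_by(.data$scaffold, .data$pos) |>
      summarise(spans = any(!is.na(.data$w_lo) & .data$pos <= .data$w_lo &
                              .data$pos + L - 1L >= .data$w_hi),
                .groups = "drop") |>
      filter(!.data$spans)
    if (nrow(cand) == 0L) next
    take <- head(cand, n_bg - got)
    out[[length(out) + 1L]] <- tibble(
      ies_id = NA_character_, type = "background", ref = "mac",
      scaffold = take$scaffold, pos = take$pos,
      sequence = substr(mac_chr[take$scaffold], take$pos, take$pos + L - 1L)
    )
    got <- got + nrow(take)
  }
  bind_rows(out)
}

# Uniform substitutions, used only to stress exact matching.
mutate_bases <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0L) return(s)
    chars <- strsplit(s, "")[[1]]
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write simulated reads as FASTQ
#'
#' Four-line records, Phred+33, fixed base quality `"I"`.
#'
#' @param reads Read tibble from [simulate_excision_reads()] (needs
#'   `read_id` and `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads$sequence)
  names(dss) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dss)))
  Biostrings::writeXStringSet(dss, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Write error-free simulated reads as SAM alignments
#'
#' Emits a headered SAM file with one perfect, primary alignment per read
#' originating from the requested reference (`cigar = <L>M`,
#' `MAPQ = 37`, flag 16 for reverse-strand reads). Intended for fixtures
#' exercising the alignment-based counting mode.
#'
#' @param reads Read tibble from [simulate_excision_reads()].
#' @param genome The reference the reads were drawn from.
#' @param reference Which origin to export: `"mac"` or `"mac_plus_ies"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, genome, reference = c("mac", "mac_plus_ies"),
                            path) {
  reference <- match.arg(reference)
  genome <- as_genome(genome)
  sel <- filter(as_tibble(reads), .data$ref == reference)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  if (nrow(sel) > 0L) {
    fwd_seq <- ifelse(sel$strand == "-", revcomp(sel$sequence), sel$sequence)
    recs <- sprintf("%s\t%d\t%s\t%d\t37\t%dM\t*\t0\t0\t%s\t%s",
                    sel$read_id, ifelse(sel$strand == "-", 16L, 0L),
                    sel$scaffold, sel$pos, nchar(fwd_seq), fwd_seq,
                    strrep("I", nchar(fwd_seq)))
  } else {
    recs <- character(0)
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Simulate per-IES junction counts directly
#'
#' The counts-level view of [simulate_excision_reads()]: for each IES,
#' `N ~ Poisson(coverage)` junction-spanning reads of which
#' `n_plus ~ Binomial(N, r)`. Identical in distribution to counting an
#' error-free simulated library; used for statistical calibration at
#' scales where materializing reads adds nothing.
#'
#' @param truth Truth table from [retention_truth()].
#' @param seed Integer seed.
#' @return A counts tibble `ies_id`, `n_plus`, `n_minus`.
#' @export
simulate_junction_counts <- function(truth, seed = 1L) {
  truth <- as_tibble(truth)
  with_seed(seed, {
    n <- rpois(nrow(truth), truth$coverage)
    n_plus <- rbinom(nrow(truth), n, truth$r)
    tibble(ies_id = truth$ies_id, n_plus = n_plus, n_minus = n - n_plus)
  })
}
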