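# Read classification against IES junction/boundary probes, and the
# per-IES IES+/IES- tallies those verdicts produce.
#
# Counting rules: a read is counted at most once per IES; only reads with
# an unambiguous probe hit are counted (a probe string shared by two
# distinct IES/kind pairs classifies nothing); matching is exact, on
# either strand, because the counts feed an exact binomial test.

#' Build a probe index for read classification
#'
#' Constructs all junction/boundary probes at flank width `k` (see
#' [make_probes()]), adds their reverse complements, and indexes the
#' distinct probe strings for constant-width dictionary matching. Probe
#' strings mapping to two or more distinct `(ies_id, kind)` pairs are
#' marked ambiguous; IESs that are uncountable at this `k` (scaffold-edge
#' or degenerate probes) are dropped with a warning and reported in the
#' index. Probes containing `N` never match any read and are excluded.
#'
#' @inheritParams make_probes
#' @return An object of class `probe_index`.
#' @export
build_probe_index <- function(annotations, mac, mac_plus_ies, k = 5L) {
  probes <- make_probes(mac, mac_plus_ies, annotations, k = k,
                        on_uncountable = "drop")
  uncountable <- filter(probes, !.data$countable) |>
    select("ies_id", "reason")
  usable <- filter(probes, .data$countable)
  long <- usable |>
    tidyr::pivot_longer(cols = c("minus_probe", "plus_left_probe",
                                 "plus_right_probe"),
                        names_to = "kind", values_to = "probe") |>
    mutate(kind = sub("_probe$", "", .data$kind)) |>
    select("ies_id", "kind", "probe") |>
    filter(!grepl("N", .data$probe, fixed = TRUE))
  rc <- mutate(long, probe = revcomp(.data$probe))
  entries <- distinct(bind_rows(long, rc))
  by_probe <- entries |>
    group_by(.data$probe) |>
    mutate(ambiguous = n_distinct(paste(.data$ies_id, .data$kind)) > 1L) |>
    ungroup()
  strings <- unique(by_probe$probe)
  lookup <- mutate(by_probe,
                   pidx = match(.data$probe, strings))
  pdict <- if (length(strings) > 0L) {
    Biostrings::PDict(Biostrings::DNAStringSet(strings))
  } else {
    NULL
  }
  structure(
    list(k = as.integer(k), probe_width = 2L * as.integer(k) + 2L,
         strings = strings, pdict = pdict, lookup = lookup,
         ies_ids = as_tibble(annotations)$ies_id, uncountable = uncountable,
         n_collisions = sum(by_probe$ambiguous)),
    class = "probe_index"
  )
}

#' @export
print.probe_index <- function(x, ...) {
  cat(sprintf(paste0("<probe_index> %d IESs, k = %d (probe width %d), ",
                     "%d probe strings, %d ambiguous entries, ",
                     "%d uncountable IESs\n"),
              length(x$ies_ids), x$k, x$probe_width, length(x$strings),
              x$n_collisions, nrow(x$uncountable)))
  invisible(x)
}

#' Classify reads against a probe index
#'
#' Each read receives exactly one verdict:
#' * `PLUS` -- it contains a boundary probe of exactly one IES (both
#'   boundary probes of the same IES still count once) and no junction
#'   probe;
#' * `MINUS` -- it contains the junction probe of exactly one IES and no
#'   boundary probe;
#' * `AMBIGUOUS` -- it hits an ambiguity-marked probe, probes of two
#'   different IESs, or both the junction and a boundary probe;
#' * `NONE` -- no probe hit (including reads shorter than the probes).
#'
#' @param reads Reads as a `DNAStringSet`, named character vector, tibble
#'   with `read_id`/`sequence`, or a FASTA/FASTQ file path.
#' @param index A [build_probe_index()] object.
#' @return A tibble `read_id`, `verdict`, `ies_id` (`NA` unless the
#'   verdict is `PLUS` or `MINUS`).
#' @export
classify_reads <- function(reads, index) {
  stopifnot(inherits(index, "probe_index"))
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) {
    reads <- read_sequencing_reads(reads)
  }
  tbl <- as_read_tbl(reads)
  if (nrow(tbl) == 0L || is.null(index$pdict)) {
    return(tibble(read_id = tbl$read_id,
                  verdict = rep("NONE", nrow(tbl)),
                  ies_id = rep(NA_character_, nrow(tbl))))
  }
  dss <- Biostrings::DNAStringSet(tbl$sequence)
  hits <- Biostrings::vwhichPDict(index$pdict, dss)
  n_hits <- lengths(hits)
  hit_tbl <- tibble(
    row = rep.int(seq_along(hits), n_hits),
    pidx = unlist(hits, use.names = FALSE)
  )
  verdicts <- hit_tbl |>
    left_join(index$lookup, by = "pidx", relationship = "many-to-many") |>
    group_by(.data$row) |>
    summarise(
      any_amb = any(.data$ambiguous),
      n_ies = n_distinct(.data$ies_id),
      has_minus = any(.data$kind == "minus"),
      has_plus = any(.data$kind != "minus"),
      the_ies = .data$ies_id[1L],
      .groups = "drop"
    ) |>
    mutate(
      verdict = case_when(
        .data$any_amb ~ "AMBIGUOUS",
        .data$n_ies > 1L ~ "AMBIGUOUS",
        .data$has_minus & .data$has_plus ~ "AMBIGUOUS",
        .data$has_plus ~ "PLUS",
        TRUE ~ "MINUS"
      ),
      ies_id = if_else(.data$verdict %in% c("PLUS", "MINUS"),
                       .data$the_ies, NA_character_)
    )
  out <- tibble(read_id = tbl$read_id, row = seq_len(nrow(tbl))) |>
    left_join(select(verdicts, "row", "verdict", "ies_id"), by = "row") |>
    mutate(verdict = if_else(is.na(.data$verdict), "NONE", .data$verdict)) |>
    select("read_id", "verdict", "ies_id")
  out
}

#' Classify a single read
#'
#' @param sequence A single read sequence.
#' @param index A [build_probe_index()] object.
#' @inherit classify_reads return
#' @export
classify_read <- function(sequence, index) {
  classify_reads(c(read = sequence), index)
}

#' Count IES+ and IES- reads per IES
#'
#' Tallies `PLUS`/`MINUS` verdicts per IES over a read set. A fragment
#' contributes at most one count per IES: mates of a pair (fragment ids
#' derived from read ids by stripping a `/1`/`/2` suffix, or supplied
#' explicitly) are classified independently but deduplicated, and a
#' fragment hitting both boundary and junction evidence for one IES is
#' resolved to `PLUS` (it contains IES sequence). `AMBIGUOUS` and `NONE`
#' verdicts are tallied globally in the attributes.
#'
#' @inheritParams classify_reads
#' @param fragment_ids Optional fragment id per read.
#' @return A tibble `ies_id`, `n_plus`, `n_minus` covering the whole IES
#'   catalog of the index, with attributes `n_reads`, `n_ambiguous`,
#'   `n_none`.
#' @export
count_reads <- function(reads, index, fragment_ids = NULL) {
  cls <- classify_reads(reads, index)
  if (is.null(fragment_ids)) {
    fragment_ids <- sub("/[12]$", "", cls$read_id)
  }
  if (length(fragment_ids) != nrow(cls)) {
    abort("fragment_ids must match the number of reads")
  }
  cls$fragment <- fragment_ids
  counted <- cls |>
    filter(.data$verdict %in% c("PLUS", "MINUS")) |>
    group_by(.data$fragment, .data$ies_id) |>
    summarise(verdict = if ("PLUS" %in% .data$verdict) "PLUS" else "MINUS",
              .groups = "drop")
  tallies <- counted |>
    group_by(.data$ies_id) |>
    summarise(n_plus = sum(.data$verdict == "PLUS"),
              n_minus = sum(.data$verdict == "MINUS"), .groups = "drop")
  out <- tibble(ies_id = index$ies_ids) |>
    left_join(tallies, by = "ies_id") |>
    mutate(n_plus = if_else(is.na(.data$n_plus), 0L, as.integer(.data$n_plus)),
           n_minus = if_else(is.na(.data$n_minus), 0L,
                             as.integer(.data$n_minus)))
  attr(out, "n_reads") <- nrow(cls)
  attr(out, "n_ambiguous") <- sum(cls$verdict == "AMBIGUOUS")
  attr(out, "n_none") <- sum(cls$verdict == "NONE")
  out
}

#' Write / read a counts table
#'
#' Tab-separated `ies_id  n_plus  n_minus`.
#'
#' @param counts Counts tibble.
#' @param path File path.
#' @return `path` (writer) or the counts tibble (reader).
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts[, c("ies_id", "n_plus", "n_minus")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "integer"))
  assert_counts(df$n_plus, "n_plus")
  assert_counts(df$n_minus, "n_minus")
  as_tibble(df)
}

#' Count IES+/IES- support from SAM alignments
#'
#' The alignment-based counting mode: reads aligned to the MAC reference
#' support the excised junction (`IES-`) of an IES when a primary,
#' non-supplementary alignment with mapping quality >= 1 covers the
#' junction TA with at least `k` aligned bases on each side; reads aligned
#' to the MAC+IES reference support the unexcised form (`IES+`) when such
#' an alignment covers either terminal TA of the IES with at least `k`
#' aligned bases on each side (the same span the boundary probes cover).
#' Each read id is counted at most once per IES; a read with
#' conflicting IES+ and IES- evidence for the same IES is discarded.
#'
#' @param annotations IES annotation tibble.
#' @param k Minimum aligned bases on each side of the junction/boundary.
#' @param sam_mac,sam_mac_plus_ies Paths to headered SAM files aligned to
#'   the MAC and MAC+IES references (either or both).
#' @return A counts tibble as in [count_reads()].
#' @export
count_from_alignments <- function(annotations, k = 5L, sam_mac = NULL,
                                  sam_mac_plus_ies = NULL) {
  if (is.null(sam_mac) && is.null(sam_mac_plus_ies)) {
    abort("provide at least one of sam_mac / sam_mac_plus_ies")
  }
  ann <- as_tibble(annotations)
  coords <- ies_coordinates(ann)
  k <- as.integer(k)
  support <- list()
  if (!is.null(sam_mac)) {
    win <- GenomicRanges::GRanges(
      coords$scaffold,
      IRanges::IRanges(coords$junction_pos - k, coords$junction_pos + 1L + k)
    )
    win$ies_id <- coords$ies_id
    support$minus <- sam_window_support(sam_mac, win, kind = "minus")
  }
  if (!is.null(sam_mac_plus_ies)) {
    win <- GenomicRanges::GRanges(
      rep(coords$scaffold, 2L),
      IRanges::IRanges(c(coords$start - k, coords$end - k - 1L),
                       c(coords$start + k + 1L, coords$end + k))
    )
    win$ies_id <- rep(coords$ies_id, 2L)
    support$plus <- sam_window_support(sam_mac_plus_ies, win, kind = "plus")
  }
  hits <- distinct(bind_rows(support))
  resolved <- hits |>
    group_by(.data$read_id, .data$ies_id) |>
    filter(n_distinct(.data$kind) == 1L) |>
    ungroup() |>
    distinct(.data$read_id, .data$ies_id, .data$kind)
  tallies <- resolved |>
    group_by(.data$ies_id) |>
    summarise(n_plus = sum(.data$kind == "plus"),
              n_minus = sum(.data$kind == "minus"), .groups = "drop")
  tibble(ies_id = ann$ies_id) |>
    left_join(tallies, by = "ies_id") |>
    mutate(n_plus = if_else(is.na(.data$n_plus), 0L, as.integer(.data$n_plus)),
           n_minus = if_else(is.na(.data$n_minus), 0L,
                             as.integer(.data$n_minus)))
}

# Reads from a SAM whose aligned segments fully contain a window.
# Returns tibble(read_id, ies_id, kind).
sam_window_support <- function(sam, windows, kind) {
  if (!file.exists(sam)) abort(sprintf("SAM file not found: %s", sam))
  bam <- Rsamtools::asBam(sam, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  mapq <- S4Vectors::mcols(gal)$mapq
  gal <- gal[!is.na(mapq) & mapq >= 1L]
  missing_sc <- setdiff(unique(as.character(GenomicRanges::seqnames(windows))),
                        GenomeInfoDb::seqlevels(gal))
  if (length(missing_sc) > 0L) {
    abort(sprintf("SAM header lacks annotation scaffold(s): %s",
                  paste(missing_sc, collapse = ", ")))
  }
  if (length(gal) == 0L) {
    return(tibble(read_id = character(), ies_id = character(),
                  kind = character()))
  }
  blocks <- GenomicAlignments::grglist(gal, drop.D.ranges = TRUE)
  ublk <- unlist(blocks, use.names = FALSE)
  read_of_block <- rep.int(seq_along(gal), S4Vectors::elementNROWS(blocks))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(windows, ublk, type = "within")
  )
  qn <- S4Vectors::mcols(gal)$qname
  tibble(
    read_id = qn[read_of_block[S4Vectors::subjectHits(ov)]],
    ies_id = windows$ies_id[S4Vectors::queryHits(ov)],
    kind = kind
  )
}
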