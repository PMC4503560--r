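# IES annotations: one row per IES on the somatic (MAC) reference.
#
# An IES is described by its 1-based junction position -- the first base of
# the TA dinucleotide left at the excision junction on the MAC sequence --
# and by its full sequence, which includes BOTH terminal TAs. Reinsertion
# replaces the single junction TA with the full IES sequence, so the
# germline-like (MAC+IES) scaffold grows by length(sequence) - 2 per IES.

IES_FEATURE_TYPE <- "internal_eliminated_sequence"

#' Read IES annotations from a GFF3 file
#'
#' Parses a GFF3 file whose `internal_eliminated_sequence` features mark
#' IES excision junctions on the MAC reference (1-based, inclusive; the
#' 2-bp feature covers the junction TA). Each feature must carry `ID` and
#' `sequence` attributes, the latter holding the full TA-bounded IES
#' sequence. All annotations are validated against `mac`.
#'
#' @param path Path to a GFF3 file.
#' @param mac MAC genome, as returned by [read_genome()].
#' @return A tibble with columns `ies_id`, `scaffold`, `junction_pos`,
#'   `sequence`, `length`, sorted by (scaffold, junction_pos).
#' @export
read_ies_annotations <- function(path, mac) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == IES_FEATURE_TYPE]
  if (length(gr) == 0L) abort("no internal_eliminated_sequence features in GFF3")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$ID) || is.null(md$sequence)) {
    abort("GFF3 features must carry ID and sequence attributes")
  }
  ann <- tibble(
    ies_id = as.character(md$ID),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    junction_pos = GenomicRanges::start(gr),
    sequence = toupper(as.character(md$sequence))
  )
  validate_ies_annotations(ann, mac)
}

#' Write IES annotations to GFF3
#'
#' @param annotations IES annotation tibble (see [read_ies_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ies_annotations <- function(annotations, path) {
  annotations <- arrange(annotations, .data$scaffold, .data$junction_pos)
  gr <- GenomicRanges::GRanges(
    annotations$scaffold,
    IRanges::IRanges(annotations$junction_pos, annotations$junction_pos + 1L),
    strand = "+"
  )
  S4Vectors::mcols(gr)$type <- IES_FEATURE_TYPE
  S4Vectors::mcols(gr)$ID <- annotations$ies_id
  S4Vectors::mcols(gr)$sequence <- annotations$sequence
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Validate IES annotations against a MAC genome
#'
#' Checks the IES invariants: unique ids; TA-bounded sequences of length
#' >= 6; the MAC sequence carries `TA` at each junction; junction
#' intervals on one scaffold do not overlap.
#'
#' @inheritParams write_ies_annotations
#' @param mac MAC genome.
#' @return The validated tibble (with a `length` column), sorted by
#'   (scaffold, junction_pos).
#' @export
validate_ies_annotations <- function(annotations, mac) {
  mac <- as_genome(mac)
  ann <- as_tibble(annotations)
  required <- c("ies_id", "scaffold", "junction_pos", "sequence")
  if (!all(required %in% names(ann))) {
    abort(sprintf("annotations need columns: %s", paste(required, collapse = ", ")))
  }
  if (nrow(ann) == 0L) {
    return(mutate(ann, length = integer(0)))
  }
  if (anyDuplicated(ann$ies_id)) abort("duplicate ies_id in annotations")
  if (any(!ann$scaffold %in% names(mac))) {
    abort(sprintf("unknown scaffold(s): %s",
                  paste(setdiff(ann$scaffold, names(mac)), collapse = ", ")))
  }
  len <- nchar(ann$sequence)
  bad <- len < 6L | str_sub(ann$sequence, 1L, 2L) != "TA" |
    str_sub(ann$sequence, -2L) != "TA" | grepl("[^ACGTN]", ann$sequence)
  if (any(bad)) {
    abort(sprintf("IES sequence not TA-bounded (or shorter than 6 bp): %s",
                  paste(ann$ies_id[bad], collapse = ", ")))
  }
  widths <- setNames(Biostrings::width(mac), names(mac))
  out <- ann$junction_pos < 1L | ann$junction_pos + 1L > widths[ann$scaffold]
  if (any(out)) {
    abort(sprintf("junction outside scaffold bounds: %s",
                  paste(ann$ies_id[out], collapse = ", ")))
  }
  mac_chr <- as.character(mac)
  site <- substr(mac_chr[ann$scaffold], ann$junction_pos, ann$junction_pos + 1L)
  if (any(site != "TA")) {
    abort(sprintf("MAC sequence at junction is not TA for: %s",
                  paste(ann$ies_id[site != "TA"], collapse = ", ")))
  }
  ann <- arrange(mutate(ann, length = len), .data$scaffold, .data$junction_pos)
  overlap <- ann |>
    group_by(.data$scaffold) |>
    mutate(gap = as.numeric(.data$junction_pos) -
             lag(as.numeric(.data$junction_pos), default = -Inf)) |>
    ungroup() |>
    filter(.data$gap < 2)
  if (nrow(overlap) > 0L) {
    abort(sprintf("overlapping junction intervals: %s",
                  paste(overlap$ies_id, collapse = ", ")))
  }
  ann
}

#' IES coordinates on the MAC+IES reference
#'
#' Converts junction positions on the MAC reference into the start/end
#' coordinates each full IES occupies on the MAC+IES reference, accounting
#' for the cumulative shift introduced by upstream insertions on the same
#' scaffold.
#'
#' @inheritParams write_ies_annotations
#' @return The annotation tibble with `start` and `end` columns (1-based,
#'   inclusive, MAC+IES coordinates).
#' @export
ies_coordinates <- function(annotations) {
  annotations |>
    mutate(length = nchar(.data$sequence)) |>
    arrange(.data$scaffold, .data$junction_pos) |>
    group_by(.data$scaffold) |>
    mutate(
      shift = cumsum(lag(.data$length - 2L, default = 0L)),
      start = .data$junction_pos + .data$shift,
      end = .data$start + .data$length - 1L
    ) |>
    ungroup() |>
    select(-"shift")
}

#' Build the MAC+IES reference by reinserting IESs
#'
#' Replaces the junction TA of each annotated IES on the MAC reference by
#' the full IES sequence (which supplies both terminal TAs). Scaffolds
#' without IESs are returned unchanged.
#'
#' @param mac MAC genome.
#' @inheritParams write_ies_annotations
#' @return The MAC+IES genome as a `DNAStringSet`.
#' @export
#' @examples
#' mac <- as_genome(c(s1 = "CCTAGG"))
#' ann <- tibble::tibble(ies_id = "i1", scaffold = "s1", junction_pos = 3,
#'                       sequence = "TAGGGTA")
#' as.character(insert_ies(mac, ann))
insert_ies <- function(mac, annotations) {
  mac <- as_genome(mac)
  ann <- validate_ies_annotations(annotations, mac)
  if (nrow(ann) == 0L) return(mac)
  per_scaffold <- split(ann, factor(ann$scaffold, levels = names(mac)))
  at <- IRanges::IRangesList(lapply(per_scaffold, function(a) {
    IRanges::IRanges(a$junction_pos, a$junction_pos + 1L)
  }))
  value <- Biostrings::DNAStringSetList(lapply(per_scaffold, function(a) {
    Biostrings::DNAStringSet(a$sequence)
  }))
  out <- Biostrings::replaceAt(mac, unname(at), unname(value))
  names(out) <- names(mac)
  out
}

#' Excise all annotated IESs from a MAC+IES reference
#'
#' Replaces each full IES sequence by a single junction TA; the exact
#' inverse of [insert_ies()]. The sequence found at each expected IES
#' location must match the annotation, otherwise an error is raised.
#'
#' @param mac_plus_ies MAC+IES genome, as produced by [insert_ies()].
#' @inheritParams write_ies_annotations
#' @return The MAC genome as a `DNAStringSet`.
#' @export
excise_ies <- function(mac_plus_ies, annotations) {
  mac_plus_ies <- as_genome(mac_plus_ies)
  ann <- as_tibble(annotations)
  if (nrow(ann) == 0L) return(mac_plus_ies)
  coords <- ies_coordinates(ann)
  if (any(!coords$scaffold %in% names(mac_plus_ies))) {
    abort("annotation scaffold missing from MAC+IES genome")
  }
  per_scaffold <- split(coords, factor(coords$scaffold, levels = names(mac_plus_ies)))
  at <- IRanges::IRangesList(lapply(per_scaffold, function(a) {
    IRanges::IRanges(a$start, a$end)
  }))
  found <- Biostrings::extractAt(mac_plus_ies, unname(at))
  expected <- lapply(per_scaffold, function(a) a$sequence)
  for (s in names(mac_plus_ies)) {
    mismatch <- as.character(found[[s]]) != expected[[s]]
    if (any(mismatch)) {
      abort(sprintf("IES sequence not found at expected coordinate: %s",
                    paste(per_scaffold[[s]]$ies_id[mismatch], collapse = ", ")))
    }
  }
  value <- Biostrings::DNAStringSetList(lapply(per_scaffold, function(a) {
    Biostrings::DNAStringSet(rep("TA", nrow(a)))
  }))
  out <- Biostrings::replaceAt(mac_plus_ies, unname(at), unname(value))
  names(out) <- names(mac_plus_ies)
  out
}
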