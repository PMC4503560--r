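# Small-RNA population profiling: length selection, contaminant
# subtraction, hierarchical exact-unique assignment to reference tiers,
# per-million normalization, and the IES/MAC enrichment ratio.

#' Keep reads in a length window
#'
#' Retains reads whose length lies in `[min_len, max_len]` (defaults
#' 20-30 nt, the small-RNA fraction), preserving input order.
#'
#' @param reads Reads (tibble with `read_id`/`sequence`, `DNAStringSet`,
#'   character vector, or FASTA/FASTQ path).
#' @param min_len,max_len Inclusive length bounds.
#' @return A read tibble.
#' @export
length_select <- function(reads, min_len = 20L, max_len = 30L) {
  if (min_len > max_len) abort("min_len must not exceed max_len")
  tbl <- srna_read_tbl(reads)
  filter(tbl, nchar(.data$sequence) >= min_len,
         nchar(.data$sequence) <= max_len)
}

#' Remove reads matching contaminant references
#'
#' Drops every read that matches any contaminant reference (either
#' strand) with at most `max_mismatch` substitutions; survivors keep
#' their input order. Typical contaminants: rDNA, food-bacteria genomes,
#' mitochondrial genome, feeding-vector sequence.
#'
#' @inheritParams length_select
#' @param contaminants Contaminant references as a `DNAStringSet`, named
#'   character vector, or FASTA path.
#' @param max_mismatch Maximum substitutions tolerated in a hit
#'   (default 1).
#' @return The surviving read tibble.
#' @export
subtract_contaminants <- function(reads, contaminants, max_mismatch = 1L) {
  tbl <- srna_read_tbl(reads)
  refs <- srna_reference_set(contaminants)
  if (length(refs) == 0L) abort("contaminant references must be non-empty")
  if (nrow(tbl) == 0L) return(tbl)
  if (max_mismatch <= 1L) {
    # enumerate every contaminant window (both strands) together with its
    # <= max_mismatch substitution neighbourhood, then test reads by hash
    # lookup; O(reference bp) rather than O(reads x references)
    lens <- sort(unique(nchar(tbl$sequence)))
    ref_chr <- c(as.character(refs), revcomp(as.character(refs)))
    variants <- vector("list", 0L)
    for (L in lens) {
      for (r in ref_chr) {
        if (nchar(r) < L) next
        windows <- substring(r, seq_len(nchar(r) - L + 1L),
                             seq_len(nchar(r) - L + 1L) + L - 1L)
        variants[[length(variants) + 1L]] <- windows
        if (max_mismatch == 1L) {
          for (p in seq_len(L)) {
            pre <- substr(windows, 1L, p - 1L)
            post <- substr(windows, p + 1L, L)
            for (b in c("A", "C", "G", "T")) {
              variants[[length(variants) + 1L]] <- paste0(pre, b, post)
            }
          }
        }
      }
    }
    hit <- tbl$sequence %in% unlist(variants)
  } else {
    hit <- map_lgl(tbl$sequence, function(s) {
      fwd <- sum(Biostrings::vcountPattern(s, refs,
                                           max.mismatch = max_mismatch))
      if (fwd > 0L) return(TRUE)
      sum(Biostrings::vcountPattern(revcomp(s), refs,
                                    max.mismatch = max_mismatch)) > 0L
    })
  }
  tbl[!hit, ]
}

# Total occurrence count of each read across a reference set, both
# strands, with a palindromic read's forward and reverse hits counted
# once. Vectorized per read-length class via constant-width dictionaries.
count_occurrences <- function(seqs, refs) {
  occ <- integer(length(seqs))
  if (length(seqs) == 0L) return(occ)
  has_n <- grepl("N", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  for (L in unique(lens[!has_n])) {
    idx <- which(lens == L & !has_n)
    fwd <- seqs[idx]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(fwd))
    n_fwd <- rowSums(Biostrings::vcountPDict(pd, refs))
    rc <- revcomp(fwd)
    pd_rc <- Biostrings::PDict(Biostrings::DNAStringSet(rc))
    n_rc <- rowSums(Biostrings::vcountPDict(pd_rc, refs))
    occ[idx] <- as.integer(n_fwd + ifelse(rc == fwd, 0L, n_rc))
  }
  occ
}

#' Hierarchically assign reads to reference tiers
#'
#' Tests each read against the tiers in order (the layout used for
#' developmental small-RNA populations: silencing-target region, then the
#' rest of the MAC genome, then the annotated IESs). A read is assigned
#' to the first tier in which it matches exactly (either strand) at
#' exactly one location across that tier's sequences. Reads matching a
#' tier at several locations are discarded as non-unique at that tier and
#' -- by default -- are not passed on to later tiers; reads matching no
#' tier are `unmapped`.
#'
#' Counts are normalized per million reads mapped to any tier.
#'
#' @inheritParams length_select
#' @param tiers Named ordered list of reference sets (`DNAStringSet`,
#'   character, or FASTA paths).
#' @param cascade_nonunique If `TRUE`, reads that are non-unique within a
#'   tier are still offered to later tiers (the alternative reading of
#'   "unique location").
#' @return An object of class `srna_profile`: a tibble with one row per
#'   tier plus `unmapped`, columns `category`, `n_raw`, `n_nonunique`,
#'   `per_million`, and attributes `total_reads`, `total_mapped`,
#'   `assignments` (per-read tibble).
#' @export
hierarchical_assign <- function(reads, tiers, cascade_nonunique = FALSE) {
  if (length(tiers) < 1L || is.null(names(tiers)) ||
      anyDuplicated(names(tiers))) {
    abort("`tiers` must be a non-empty, uniquely named ordered list")
  }
  tbl <- srna_read_tbl(reads)
  tier_sets <- lapply(tiers, srna_reference_set)
  assignment <- rep(NA_character_, nrow(tbl))
  nonunique_at <- rep(NA_character_, nrow(tbl))
  pending <- rep(TRUE, nrow(tbl))
  for (tier_name in names(tier_sets)) {
    idx <- which(pending)
    if (length(idx) == 0L) break
    occ <- count_occurrences(tbl$sequence[idx], tier_sets[[tier_name]])
    unique_hit <- idx[occ == 1L]
    multi_hit <- idx[occ > 1L]
    assignment[unique_hit] <- tier_name
    pending[unique_hit] <- FALSE
    if (length(multi_hit) > 0L) {
      first_multi <- is.na(nonunique_at[multi_hit])
      nonunique_at[multi_hit[first_multi]] <- tier_name
      if (!cascade_nonunique) pending[multi_hit] <- FALSE
    }
  }
  assignments <- tibble(
    read_id = tbl$read_id,
    category = case_when(
      !is.na(assignment) ~ assignment,
      !is.na(nonunique_at) & !cascade_nonunique ~ "nonunique",
      TRUE ~ "unmapped"
    ),
    nonunique_tier = nonunique_at
  )
  raw <- vapply(names(tiers), function(tn) sum(assignments$category == tn),
                integer(1))
  nonuni <- vapply(names(tiers), function(tn) {
    sum(assignments$category == "nonunique" &
          assignments$nonunique_tier == tn, na.rm = TRUE)
  }, integer(1))
  n_unmapped <- sum(assignments$category == "unmapped")
  total_mapped <- sum(raw)
  per_million <- if (total_mapped > 0) raw * 1e6 / total_mapped else
    rep(NA_real_, length(raw))
  profile <- bind_rows(
    tibble(category = names(tiers), n_raw = unname(raw),
           n_nonunique = unname(nonuni), per_million = unname(per_million)),
    tibble(category = "unmapped", n_raw = n_unmapped, n_nonunique = 0L,
           per_million = NA_real_)
  )
  structure(profile,
            total_reads = nrow(tbl),
            total_mapped = total_mapped,
            assignments = assignments,
            class = c("srna_profile", class(profile)))
}

#' Full small-RNA profiling pipeline
#'
#' Length selection, optional contaminant subtraction, then hierarchical
#' tier assignment -- in that fixed order.
#'
#' @inheritParams hierarchical_assign
#' @inheritParams subtract_contaminants
#' @param contaminants Optional contaminant references.
#' @inheritParams length_select
#' @return An `srna_profile` (see [hierarchical_assign()]).
#' @export
srna_profile <- function(reads, tiers, contaminants = NULL, min_len = 20L,
                         max_len = 30L, max_mismatch = 1L,
                         cascade_nonunique = FALSE) {
  tbl <- length_select(reads, min_len, max_len)
  if (!is.null(contaminants)) {
    tbl <- subtract_contaminants(tbl, contaminants, max_mismatch)
  }
  hierarchical_assign(tbl, tiers, cascade_nonunique)
}

#' @export
print.srna_profile <- function(x, ...) {
  cat(sprintf("<srna_profile> %d reads, %d mapped to a reference\n",
              attr(x, "total_reads"), attr(x, "total_mapped")))
  NextMethod()
}

#' IES/MAC enrichment ratio between two time points
#'
#' `[(IES/MAC)_late] / [(IES/MAC)_early]` on per-million-normalized
#' counts; quantifies the enrichment of germline-restricted sequences in
#' a scanning small-RNA population between an early and a later
#' developmental time point.
#'
#' @param early,late `srna_profile` objects.
#' @param ies,mac Category names holding the IES and MAC counts.
#' @return A single ratio.
#' @export
enrichment_ratio <- function(early, late, ies = "ies", mac = "mac") {
  ratio_of <- function(p, label) {
    m <- p$per_million[p$category == mac]
    i <- p$per_million[p$category == ies]
    if (length(m) != 1L || length(i) != 1L || is.na(m) || is.na(i) ||
        m == 0 || i == 0) {
      abort(sprintf("undefined IES/MAC ratio in the %s profile", label))
    }
    unname(i / m)
  }
  ratio_of(late, "late") / ratio_of(early, "early")
}

# Coercions local to the sRNA stage -----------------------------------------

srna_read_tbl <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && is.null(names(reads)) &&
      file.exists(reads)) {
    return(read_sequencing_reads(reads))
  }
  as_read_tbl(reads)
}

srna_reference_set <- function(refs) {
  if (methods::is(refs, "DNAStringSet")) return(refs)
  if (is.character(refs) && length(refs) == 1L && is.null(names(refs)) &&
      file.exists(refs)) {
    return(read_genome(refs))
  }
  if (is.character(refs)) return(Biostrings::DNAStringSet(toupper(refs)))
  abort("references must be a DNAStringSet, character vector or FASTA path")
}
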