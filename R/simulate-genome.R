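# Synthetic genomes and IES catalogs.
#
# Fixtures emulate the statistical structure the analysis assumes: an
# AT-rich somatic genome, TA-bounded IESs with the field's periodic size
# distribution (shortest class 26-32 bp, then peaks roughly every 10 bp),
# and a germline-like MAC+IES companion built by reinsertion.

#' Simulate an AT-rich genome
#'
#' Draws i.i.d. bases with `P(A) = P(T) = at_fraction / 2` and
#' `P(C) = P(G) = (1 - at_fraction) / 2`. Reproducible given `seed`.
#'
#' @param n_scaffolds Number of scaffolds (>= 1).
#' @param scaffold_length Length of each scaffold in bp (>= 200).
#' @param at_fraction Expected A+T fraction in `[0, 1]`; the default 0.72
#'   mirrors the AT-rich somatic genome of *Paramecium*.
#' @param seed Integer seed.
#' @return A named `DNAStringSet`.
#' @export
simulate_genome <- function(n_scaffolds = 1L, scaffold_length = 100000L,
                            at_fraction = 0.72, seed = 1L) {
  assert_scalar_number(n_scaffolds, "n_scaffolds", lower = 1)
  assert_scalar_number(scaffold_length, "scaffold_length", lower = 200)
  assert_scalar_number(at_fraction, "at_fraction", lower = 0, upper = 1)
  prob <- c(A = at_fraction / 2, T = at_fraction / 2,
            C = (1 - at_fraction) / 2, G = (1 - at_fraction) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_scaffolds), function(i) {
      paste(sample(names(prob), scaffold_length, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("scaffold_%02d", seq_len(n_scaffolds))
    as_genome(seqs)
  })
}

#' Default IES length sampler
#'
#' Samples IES lengths from a mixture over the periodic size classes seen
#' in ciliate IES catalogs: a dominant shortest class centred at 28 bp
#' (26-32 bp) followed by peaks roughly every 10 bp with geometrically
#' decaying weight. All lengths are >= 26.
#'
#' @param n Number of lengths to draw.
#' @return An integer vector of IES lengths.
#' @export
default_ies_lengths <- function(n) {
  peaks <- c(28L, 38L, 48L, 58L, 68L, 78L, 88L, 98L)
  weights <- c(0.45, 0.15, 0.12, 0.10, 0.08, 0.05, 0.03, 0.02)
  centre <- sample(peaks, n, replace = TRUE, prob = weights)
  pmax(26L, centre + sample(-2:2, n, replace = TRUE))
}

#' Simulate an IES catalog and the matching MAC+IES genome
#'
#' Plants `n` TA junctions on the MAC genome, separated by at least
#' `min_spacing` bp and at least `edge_margin` bp away from scaffold ends,
#' assigns each junction a random TA-bounded IES with length drawn from
#' `length_sampler`, and builds the MAC+IES reference by reinsertion.
#'
#' Because junction sites are planted (the local dinucleotide is
#' overwritten with `TA` where needed), the MAC genome actually hosting
#' the catalog is returned alongside the annotations.
#'
#' @param mac MAC genome (e.g. from [simulate_genome()]).
#' @param n Number of IESs.
#' @param length_sampler Function `n -> integer lengths >= 6`; defaults to
#'   [default_ies_lengths()].
#' @param min_spacing Minimum distance between junctions on a scaffold.
#' @param edge_margin Minimum distance between a junction and a scaffold
#'   end; keep this above the read length used downstream.
#' @param interior_at A+T fraction of IES-internal bases (IESs are more
#'   AT-rich than flanking somatic DNA).
#' @param seed Integer seed.
#' @return A list with `mac` (the genome carrying the planted junctions),
#'   `annotations` (tibble) and `mac_plus_ies`.
#' @export
simulate_ies_catalog <- function(mac, n, length_sampler = default_ies_lengths,
                                 min_spacing = 300L, edge_margin = 150L,
                                 interior_at = 0.8, seed = 1L) {
  mac <- as_genome(mac)
  assert_scalar_number(n, "n", lower = 0)
  n <- as.integer(n)
  widths <- Biostrings::width(mac)
  spans <- pmax(0L, widths - 2L * as.integer(edge_margin))
  capacity <- pmax(0L, spans %/% as.integer(min_spacing))
  if (sum(capacity) < n) {
    abort(sprintf(paste0("cannot place %d junctions with min_spacing %d and ",
                         "edge_margin %d; use a longer genome"),
                  n, min_spacing, edge_margin))
  }
  if (n == 0L) {
    ann <- tibble(ies_id = character(), scaffold = character(),
                  junction_pos = integer(), sequence = character())
    return(list(mac = mac, annotations = mutate(ann, length = integer(0)),
                mac_plus_ies = mac))
  }
  with_seed(seed, {
    # allocate junctions to scaffolds proportionally to capacity
    n_per <- floor(capacity * n / sum(capacity))
    while (sum(n_per) < n) {
      room <- which(n_per < capacity)
      i <- room[which.max(capacity[room] - n_per[room])]
      n_per[i] <- n_per[i] + 1L
    }
    mac_chr <- as.character(mac)
    ann <- vector("list", length(mac))
    for (i in seq_along(mac)) {
      if (n_per[i] == 0L) next
      # sorted positions with guaranteed spacing: uniform draws plus offsets
      slack <- spans[i] - (n_per[i] - 1L) * as.integer(min_spacing)
      base <- sort(sample.int(slack, n_per[i], replace = TRUE))
      pos <- as.integer(edge_margin) + base +
        (seq_len(n_per[i]) - 1L) * as.integer(min_spacing)
      for (p in pos) substr(mac_chr[i], p, p + 1L) <- "TA"  # plant junction TA
      lens <- as.integer(length_sampler(n_per[i]))
      if (any(lens < 6L)) abort("length_sampler produced lengths < 6")
      interior <- vapply(lens, function(l) {
        paste(sample(c("A", "T", "C", "G"), l - 4L, replace = TRUE,
                     prob = c(interior_at / 2, interior_at / 2,
                              (1 - interior_at) / 2, (1 - interior_at) / 2)),
              collapse = "")
      }, character(1))
      ann[[i]] <- tibble(
        ies_id = sprintf("ies_%s_%d", names(mac)[i], pos),
        scaffold = names(mac)[i],
        junction_pos = pos,
        sequence = paste0("TA", interior, "TA")
      )
    }
    mac2 <- as_genome(mac_chr)
    names(mac2) <- names(mac)
    annotations <- validate_ies_annotations(bind_rows(ann), mac2)
    list(mac = mac2, annotations = annotations,
         mac_plus_ies = insert_ies(mac2, annotations))
  })
}
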