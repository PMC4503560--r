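# Synthetic small-RNA libraries: mixtures over source pools.

#' Simulate a small-RNA library from category pools
#'
#' Draws `n_reads` reads whose source category follows `proportions` (a
#' named probability vector, e.g. over `target`, `mac`, `ies`,
#' `contaminant`), whose length follows `length_weights` over
#' `min_len:max_len` nt, and whose sequence is an exact substring of a
#' randomly chosen sequence from the corresponding pool (either strand).
#' The category of origin is recorded in the returned truth table and in
#' the read id.
#'
#' @param n_reads Number of reads.
#' @param proportions Named non-negative vector summing to 1.
#' @param pools Named list of `DNAStringSet` source pools; every category
#'   with positive proportion needs a non-empty pool.
#' @param min_len,max_len Read length range (defaults 20 and 30 nt).
#' @param length_weights Optional weights over `min_len:max_len`; the
#'   default peaks at 25 nt.
#' @param seed Integer seed.
#' @param fastq Optional FASTQ output path.
#' @return A list with `reads` (tibble: read_id, sequence, length,
#'   category, source, start, strand) and `truth` (read_id, category).
#' @export
simulate_srna <- function(n_reads, proportions, pools, min_len = 20L,
                          max_len = 30L, length_weights = NULL, seed = 1L,
                          fastq = NULL) {
  assert_scalar_number(n_reads, "n_reads", lower = 1)
  if (is.null(names(proportions)) || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8) {
    abort("`proportions` must be a named non-negative vector summing to 1")
  }
  if (min_len > max_len) abort("min_len must not exceed max_len")
  active <- names(proportions)[proportions > 0]
  missing_pool <- setdiff(active, names(pools))
  if (length(missing_pool) > 0L) {
    abort(sprintf("no sequence pool for categor(ies): %s",
                  paste(missing_pool, collapse = ", ")))
  }
  lens_support <- seq.int(min_len, max_len)
  if (is.null(length_weights)) {
    length_weights <- exp(-abs(lens_support - 25L) / 2)
  }
  if (length(length_weights) != length(lens_support)) {
    abort("length_weights must match min_len:max_len")
  }
  with_seed(seed, {
    category <- sample(names(proportions), n_reads, replace = TRUE,
                       prob = proportions)
    len <- sample(lens_support, n_reads, replace = TRUE, prob = length_weights)
    reads <- vector("list", length(active))
    for (j in seq_along(active)) {
      cat_j <- active[j]
      idx <- which(category == cat_j)
      if (length(idx) == 0L) next
      pool <- pools[[cat_j]]
      pw <- Biostrings::width(pool)
      if (any(len[idx] > max(pw))) {
        abort(sprintf("requested read length exceeds every sequence in pool '%s'",
                      cat_j))
      }
      src <- integer(length(idx))
      st <- integer(length(idx))
      for (ii in seq_along(idx)) {
        l <- len[idx[ii]]
        ok <- which(pw >= l)
        src[ii] <- if (length(ok) == 1L) ok else {
          sample(ok, 1L, prob = pw[ok] - l + 1)
        }
        st[ii] <- sample.int(pw[src[ii]] - l + 1L, 1L)
      }
      seqs <- as.character(Biostrings::subseq(pool[src], start = st,
                                              width = len[idx]))
      strand <- ifelse(runif(length(idx)) < 0.5, "+", "-")
      seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
      reads[[j]] <- tibble(
        idx = idx, sequence = unname(seqs), length = len[idx],
        category = cat_j,
        source = (names(pool) %||% as.character(seq_along(pool)))[src],
        start = st, strand = strand
      )
    }
    reads <- arrange(bind_rows(reads), .data$idx)
    reads <- mutate(reads,
                    read_id = sprintf("srna%06d:%s", .data$idx, .data$category)) |>
      select("read_id", "sequence", "length", "category", "source",
             "start", "strand")
    if (!is.null(fastq)) write_reads_fastq(reads, fastq)
    list(reads = reads, truth = select(reads, "read_id", "category"))
  })
}
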