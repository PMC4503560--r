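# Synthetic per-contig coverage profiles for the complexity stage.

#' Simulate per-dataset contig read counts with planted coverage
#'
#' Builds a panel of contigs and, for each dataset, read counts that place
#' every contig flagged covered above the 2-RPKM coverage threshold and
#' every other contig below it, under the emitted library size. The
#' planted design is the construction oracle for the complexity stage.
#'
#' @param n_contigs Number of contigs (>= 1).
#' @param covered Named list of logical vectors (one per dataset, each of
#'   length `n_contigs`): the planted covered flags.
#' @param length_sampler Function `n -> integer bp lengths`; the default
#'   draws uniformly in 1,100-9,000 bp so every contig passes the 1-kb
#'   filter unless the caller supplies shorter ones.
#' @param total_mapped Library size (total mapped reads) reported for each
#'   dataset.
#' @param covered_rpkm,uncovered_rpkm Target RPKM ranges for covered and
#'   uncovered contigs; the defaults leave a guard band around 2 RPKM so
#'   integer rounding cannot cross the threshold.
#' @param seed Integer seed.
#' @return A long tibble: `dataset`, `contig_id`, `length`, `reads`,
#'   `total_mapped`, `covered_true`.
#' @export
simulate_contig_coverage <- function(n_contigs, covered,
                                     length_sampler = NULL,
                                     total_mapped = 1e6,
                                     covered_rpkm = c(5, 50),
                                     uncovered_rpkm = c(0, 1.5),
                                     seed = 1L) {
  assert_scalar_number(n_contigs, "n_contigs", lower = 1)
  if (!is.list(covered) || is.null(names(covered)) ||
      !all(vapply(covered, function(x) is.logical(x) && length(x) == n_contigs,
                  logical(1)))) {
    abort("`covered` must be a named list of logical vectors of length n_contigs")
  }
  if (is.null(length_sampler)) {
    length_sampler <- function(n) as.integer(round(runif(n, 1100, 9000)))
  }
  with_seed(seed, {
    lengths <- as.integer(length_sampler(n_contigs))
    contig_id <- sprintf("contig_%04d", seq_len(n_contigs))
    out <- lapply(names(covered), function(ds) {
      flag <- covered[[ds]]
      target <- ifelse(flag,
                       runif(n_contigs, covered_rpkm[1], covered_rpkm[2]),
                       runif(n_contigs, uncovered_rpkm[1], uncovered_rpkm[2]))
      reads <- as.integer(round(target * (lengths / 1000) *
                                  (total_mapped / 1e6)))
      tibble(dataset = ds, contig_id = contig_id, length = lengths,
             reads = reads, total_mapped = as.integer(total_mapped),
             covered_true = flag)
    })
    bind_rows(out)
  })
}
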