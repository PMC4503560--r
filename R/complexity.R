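# Coverage-based sequence complexity and comparative set/size analyses.
#
# Complexity of a germline-enriched contig panel is measured per dataset:
# a contig counts as covered when its coverage exceeds 2 RPKM and it is
# longer than 1 kb; the complexity private to a dataset relative to a
# control is the summed length of contigs covered by the dataset but not
# by the control (the germline-restricted regions).

#' Reads per kilobase per million mapped reads
#'
#' @param reads Mapped reads on the contig (vectorized).
#' @param length_bp Contig length in bp (>= 1).
#' @param total_mapped Total mapped reads in the library (>= 1).
#' @return Numeric RPKM values.
#' @export
#' @examples
#' rpkm(10, 2000, 1e6)  # 5
rpkm <- function(reads, length_bp, total_mapped) {
  if (any(length_bp < 1)) abort("`length_bp` must be >= 1")
  if (any(total_mapped < 1)) abort("`total_mapped` must be >= 1")
  assert_counts(reads, "reads")
  reads / (length_bp / 1000) / (total_mapped / 1e6)
}

#' Annotate contig coverage with RPKM and covered flags
#'
#' @param counts Tibble with `contig_id`, `length`, `reads`,
#'   `total_mapped` (and optionally `dataset`).
#' @param min_len Length cutoff in bp; contigs must be strictly longer
#'   (default 1000).
#' @param min_rpkm Coverage cutoff; contigs must be strictly above
#'   (default 2).
#' @return The tibble with `rpkm` and `covered` columns added.
#' @export
contig_coverage <- function(counts, min_len = 1000, min_rpkm = 2) {
  counts <- as_tibble(counts)
  mutate(counts,
         rpkm = rpkm(.data$reads, .data$length, .data$total_mapped),
         covered = .data$length > min_len & .data$rpkm > min_rpkm)
}

#' Covered contig set
#'
#' Contigs strictly longer than `min_len` with coverage strictly above
#' `min_rpkm`.
#'
#' @inheritParams contig_coverage
#' @return Character vector of contig ids.
#' @export
covered_set <- function(counts, min_len = 1000, min_rpkm = 2) {
  cc <- contig_coverage(counts, min_len, min_rpkm)
  cc$contig_id[cc$covered]
}

#' Complexity private to a dataset
#'
#' Summed length (bp) of contigs covered by a dataset but not by the
#' control -- the sequence complexity restricted to the unrearranged
#' (germline) genome under that dataset.
#'
#' @param covered,covered_control Character vectors of covered contig
#'   ids.
#' @param lengths Contig lengths: a named numeric vector or a tibble with
#'   `contig_id` and `length`.
#' @return Total bp (numeric scalar).
#' @export
private_complexity <- function(covered, covered_control, lengths) {
  len <- contig_length_vector(lengths)
  ids <- setdiff(covered, covered_control)
  missing_len <- setdiff(ids, names(len))
  if (length(missing_len) > 0L) {
    abort(sprintf("no length for contig(s): %s",
                  paste(missing_len, collapse = ", ")))
  }
  sum(len[ids])
}

#' Fraction of reference-private complexity shared by a test dataset
#'
#' With `P = covered_ref \\ covered_control` the germline-restricted
#' panel, returns `len(covered_test intersect P) / len(P)` -- e.g. the
#' fraction of germline-restricted sequence whose elimination requires
#' the factor knocked down in the test dataset.
#'
#' @param covered_test,covered_ref,covered_control Covered contig id
#'   vectors.
#' @inheritParams private_complexity
#' @return A fraction in `[0, 1]`.
#' @export
private_complexity_fraction <- function(covered_test, covered_ref,
                                        covered_control, lengths) {
  len <- contig_length_vector(lengths)
  ref_private <- setdiff(covered_ref, covered_control)
  if (length(ref_private) == 0L) {
    abort("reference-private contig set is empty; fraction undefined")
  }
  shared <- intersect(covered_test, ref_private)
  sum(len[shared]) / sum(len[ref_private])
}

contig_length_vector <- function(lengths) {
  if (is.data.frame(lengths)) {
    return(setNames(as.numeric(lengths$length), lengths$contig_id))
  }
  if (is.numeric(lengths) && !is.null(names(lengths))) {
    return(lengths)
  }
  abort("`lengths` must be a named numeric vector or a contig/length tibble")
}

#' Venn-partition cardinalities of named id sets
#'
#' Cardinality of every exclusive region of the Venn partition of two or
#' more sets.
#'
#' @param sets Named list (>= 2) of character id vectors.
#' @return A tibble `region` (e.g. `"A&B"`), `n`; regions partition the
#'   union.
#' @export
overlap_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets))) {
    abort("`sets` must be a named list of at least two id vectors")
  }
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  combos <- unlist(lapply(seq_along(sets), function(sz) {
    utils::combn(names(sets), sz, paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = combos))
  tibble(region = combos, n = as.integer(counts))
}

#' Pairwise overlap percentages between id sets
#'
#' For every ordered pair, `100 * |A ∩ B| / |B|`: the percentage of set B
#' falling in set A, the marginal reported when comparing a focal call
#' set with the call sets of other knockdowns.
#'
#' @inheritParams overlap_counts
#' @return A tibble `set_a`, `set_b`, `n_a`, `n_b`, `n_intersect`,
#'   `pct_of_b`.
#' @export
overlap_percentages <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets))) {
    abort("`sets` must be a named list of at least two id vectors")
  }
  pairs <- expand.grid(set_a = names(sets), set_b = names(sets),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$set_a != pairs$set_b, ]
  as_tibble(pairs) |>
    mutate(
      n_a = map_int(.data$set_a, ~ length(sets[[.x]])),
      n_b = map_int(.data$set_b, ~ length(sets[[.x]])),
      n_intersect = map2(.data$set_a, .data$set_b,
                         ~ length(intersect(sets[[.x]], sets[[.y]]))) |>
        unlist(),
      pct_of_b = if_else(.data$n_b > 0, 100 * .data$n_intersect / .data$n_b,
                         NA_real_)
    )
}

#' Binned quartile summaries of one variable against another
#'
#' Bins the rows of `df` by `bin_var` -- either into its empirical
#' quartiles (`breaks = "quartiles"`, type-7 quantiles, left-closed
#' intervals) or at explicit break points -- and summarizes `value_var`
#' per bin with n, median, and first/third quartiles (type 7 throughout).
#' Empty bins are reported with `n = 0` and `NA` statistics.
#'
#' Used in both orientations: IES size per retention-score quartile, and
#' retention score per IES size group.
#'
#' @param df A data frame.
#' @param bin_var,value_var Column names (strings).
#' @param breaks `"quartiles"` or a numeric vector of cut points covering
#'   the data.
#' @return A tibble `bin`, `bin_low`, `bin_high`, `n`, `median`, `q1`,
#'   `q3`.
#' @export
size_bin_stats <- function(df, bin_var, value_var, breaks = "quartiles") {
  df <- as_tibble(df)
  if (!all(c(bin_var, value_var) %in% names(df))) {
    abort("bin_var and value_var must name columns of df")
  }
  x <- df[[bin_var]]
  if (identical(breaks, "quartiles")) {
    breaks <- unique(quantile(x, probs = seq(0, 1, 0.25), type = 7,
                              na.rm = TRUE))
  }
  if (length(breaks) < 2L) abort("breaks must define at least one bin")
  if (min(x, na.rm = TRUE) < min(breaks) || max(x, na.rm = TRUE) > max(breaks)) {
    abort("breaks must cover the data range")
  }
  keep <- !is.na(x)
  bins <- cut(x[keep], breaks = breaks, right = FALSE, include.lowest = TRUE)
  df[keep, ] |>
    mutate(.bin = bins) |>
    group_by(.bin = .data$.bin, .drop = FALSE) |>
    summarise(
      n = dplyr::n(),
      median = if (dplyr::n() > 0) median(.data[[value_var]]) else NA_real_,
      q1 = if (dplyr::n() > 0) {
        unname(quantile(.data[[value_var]], 0.25, type = 7))
      } else NA_real_,
      q3 = if (dplyr::n() > 0) {
        unname(quantile(.data[[value_var]], 0.75, type = 7))
      } else NA_real_,
      .groups = "drop"
    ) |>
    mutate(bin = as.character(.data$.bin),
           bin_low = head(breaks, -1L),
           bin_high = tail(breaks, -1L)) |>
    select("bin", "bin_low", "bin_high", "n", "median", "q1", "q3")
}

#' Two-sided Mann-Whitney rank-sum p-value
#'
#' Exact enumeration when both groups have at most 8 observations and no
#' ties are present; normal approximation with continuity and tie
#' correction otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return The two-sided p-value.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact, 0.1
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty")
  }
  exact <- length(group_a) <= 8L && length(group_b) <= 8L &&
    !any(duplicated(c(group_a, group_b)))
  suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value
  )
}

#' Sequential rank-sum comparisons across ordered groups
#'
#' Compares each group's value distribution with the previous group's
#' (Mann-Whitney, two-sided), BH-adjusts across the sequence of
#' comparisons, and flags significance at `threshold` -- the procedure
#' behind "this size class differs from the previous one" annotations.
#'
#' @param df A data frame.
#' @param group_var,value_var Column names (strings); groups are compared
#'   in the order of `levels` if given, else sorted unique order.
#' @param levels Optional explicit group order.
#' @param threshold Significance threshold on the adjusted p-value.
#' @return A tibble `group`, `n`, `median`, `p_vs_previous`, `padj`,
#'   `significant`.
#' @export
sequential_rank_tests <- function(df, group_var, value_var, levels = NULL,
                                  threshold = 0.05) {
  df <- as_tibble(df)
  g <- df[[group_var]]
  lv <- levels %||% (if (is.factor(g)) base::levels(g) else sort(unique(g)))
  values <- lapply(lv, function(l) df[[value_var]][g == l])
  if (any(lengths(values) == 0L)) abort("every group must be non-empty")
  p <- c(NA_real_, vapply(seq_along(lv)[-1L], function(i) {
    rank_sum_test(values[[i]], values[[i - 1L]])
  }, numeric(1)))
  padj <- rep(NA_real_, length(p))
  padj[-1L] <- bh_adjust(p[-1L])
  tibble(
    group = as.character(lv),
    n = lengths(values),
    median = vapply(values, median, numeric(1)),
    p_vs_previous = p,
    padj = padj,
    significant = if_else(is.na(padj), NA, padj < threshold)
  )
}
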