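# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Clopper-Pearson bounds by bisection on the binomial CDF:
#   high = the p solving P(X <= x; n, p) = tail  (1 for x = n)
#   low  = the p solving P(X >= x; n, p) = tail  (0 for x = 0)
cp_bisect <- function(x, n, alpha = 0.95) {
  tail <- (1 - alpha) / 2
  # f must be decreasing in p; bisect to f(p) = target
  solve_p <- function(f, target) {
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  high <- if (x == n) 1 else solve_p(function(p) pbinom(x, n, p), tail)
  low <- if (x == 0) 0 else {
    solve_p(function(p) pbinom(x - 1, n, p), 1 - tail)
  }
  c(low = low, high = high)
}

# Upper-tail binomial p-value by direct pmf summation.
tail_sum <- function(x, n, p0) {
  if (x == 0) return(1)
  sum(dbinom(x:n, n, p0))
}

# Benjamini-Hochberg step-up computed by hand (sort, scale, cumulative
# minimum from the largest p, restore order).
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(1, adj)[order(o)]
}

# Brute-force read counting: search every probe string (and its reverse
# complement) in every read with base-R fixed substring matching, then
# apply the counting rules independently of the package's index.
brute_force_counts <- function(read_seqs, probes) {
  stopifnot(all(probes$countable))
  entries <- list()
  for (i in seq_len(nrow(probes))) {
    for (kind in c("minus", "plus_left", "plus_right")) {
      p <- probes[[paste0(kind, "_probe")]][i]
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
      entries[[length(entries) + 1L]] <- data.frame(
        ies_id = probes$ies_id[i],
        kind = ifelse(kind == "minus", "minus", "plus"),
        probe = unique(c(p, rc)), stringsAsFactors = FALSE
      )
    }
  }
  entries <- unique(do.call(rbind, entries))
  # probe strings claimed by two or more (ies, kind) pairs are ambiguous
  key <- paste(entries$ies_id, entries$kind)
  tab <- tapply(key, entries$probe, function(k) length(unique(k)))
  amb_strings <- names(tab)[tab > 1]

  verdicts <- character(length(read_seqs))
  hit_ies <- character(length(read_seqs))
  for (j in seq_along(read_seqs)) {
    hits <- entries[vapply(entries$probe,
                           function(p) grepl(p, read_seqs[j], fixed = TRUE),
                           logical(1)), ]
    if (nrow(hits) == 0L) {
      verdicts[j] <- "NONE"
    } else if (any(hits$probe %in% amb_strings) ||
               length(unique(hits$ies_id)) > 1L ||
               (any(hits$kind == "minus") && any(hits$kind == "plus"))) {
      verdicts[j] <- "AMBIGUOUS"
    } else if (any(hits$kind == "plus")) {
      verdicts[j] <- "PLUS"; hit_ies[j] <- hits$ies_id[1]
    } else {
      verdicts[j] <- "MINUS"; hit_ies[j] <- hits$ies_id[1]
    }
  }
  counted <- data.frame(ies_id = hit_ies, verdict = verdicts,
                        stringsAsFactors = FALSE)
  counted <- counted[counted$verdict %in% c("PLUS", "MINUS"), ]
  out <- data.frame(ies_id = probes$ies_id, stringsAsFactors = FALSE)
  out$n_plus <- vapply(out$ies_id, function(i) {
    sum(counted$ies_id == i & counted$verdict == "PLUS")
  }, integer(1))
  out$n_minus <- vapply(out$ies_id, function(i) {
    sum(counted$ies_id == i & counted$verdict == "MINUS")
  }, integer(1))
  out
}

# Brute-force Hamming-distance contaminant scan over every alignment
# offset of every read against every reference, both strands.
brute_force_contaminant_hits <- function(read_seqs, ref_seqs, max_mismatch) {
  hamming_hit <- function(read, ref) {
    nr <- nchar(read)
    if (nr > nchar(ref)) return(FALSE)
    for (off in 0:(nchar(ref) - nr)) {
      window <- substr(ref, off + 1, off + nr)
      d <- sum(strsplit(read, "")[[1]] != strsplit(window, "")[[1]])
      if (d <= max_mismatch) return(TRUE)
    }
    FALSE
  }
  vapply(read_seqs, function(s) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    any(vapply(ref_seqs, function(r) {
      hamming_hit(s, r) || hamming_hit(rc, r)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

# Small standard fixture: GC-balanced genome + catalog + truth, used where
# exact probe specificity matters.
balanced_fixture <- function(n_ies = 25, r = 0.4, coverage = 25, k = 8,
                             seed = 17) {
  g <- simulate_genome(2, 20000, at_fraction = 0.5, seed = seed)
  cat0 <- simulate_ies_catalog(g, n_ies, interior_at = 0.5, seed = seed + 1)
  truth <- retention_truth(cat0$annotations, r = r, coverage = coverage)
  sim <- simulate_excision_reads(cat0$mac, cat0$mac_plus_ies,
                                 cat0$annotations, truth, overhang = k,
                                 seed = seed + 2)
  list(catalog = cat0, truth = truth, sim = sim, k = k)
}
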