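make_index_fixture <- function() {
  g <- simulate_genome(1, 20000, at_fraction = 0.5, seed = 101)
  cat0 <- simulate_ies_catalog(g, 12, interior_at = 0.5, seed = 102)
  list(catalog = cat0,
       index = build_probe_index(cat0$annotations, cat0$mac,
                                 cat0$mac_plus_ies, k = 5))
}

test_that("a probe index holds 6n keys for n specific IESs", {
  fx <- make_index_fixture()
  expect_length(fx$index$strings, 6 * nrow(fx$catalog$annotations))
  expect_identical(fx$index$n_collisions, 0L)
  empty <- build_probe_index(fx$catalog$annotations[0, ], fx$catalog$mac,
                             fx$catalog$mac_plus_ies, k = 5)
  expect_length(empty$strings, 0)
})

test_that("probes shared between IESs are marked ambiguous", {
  # two IESs with identical flanks and identical sequence -> shared probes
  mac <- as_genome(c(
    s1 = paste0(strrep("C", 30), "GGGGTAGGGG", strrep("C", 30),
                "GGGGTAGGGG", strrep("C", 30))
  ))
  pos <- c(35L, 75L)
  ann <- tibble::tibble(
    ies_id = c("a", "b"), scaffold = "s1", junction_pos = pos,
    sequence = "TACGATCGCGTA"
  )
  gl <- insert_ies(mac, ann)
  idx <- build_probe_index(ann, mac, gl, k = 3)
  expect_gt(idx$n_collisions, 0L)
  # a read carrying the shared boundary probe is AMBIGUOUS
  probe <- make_probes(mac, gl, ann, k = 3)$plus_left_probe[1]
  cls <- classify_read(paste0("CCCC", probe, "CCCC"), idx)
  expect_identical(cls$verdict, "AMBIGUOUS")
})

test_that("single-read verdicts follow the counting rules", {
  fx <- make_index_fixture()
  ann <- fx$catalog$annotations
  probes <- make_probes(fx$catalog$mac, fx$catalog$mac_plus_ies, ann, k = 5)
  i <- probes$ies_id[1]
  # minus probe embedded in extra flank -> MINUS
  minus_read <- paste0("GGCC", probes$minus_probe[1], "TTGG")
  expect_identical(classify_read(minus_read, fx$index)$verdict, "MINUS")
  expect_identical(classify_read(minus_read, fx$index)$ies_id, i)
  # read spanning an entire short IES carries both plus probes -> one PLUS
  coords <- ies_coordinates(ann)[1, ]
  gl_chr <- as.character(fx$catalog$mac_plus_ies)[[coords$scaffold]]
  whole <- substr(gl_chr, coords$start - 20, coords$end + 20)
  cls <- classify_read(whole, fx$index)
  expect_identical(cls$verdict, "PLUS")
  expect_identical(cls$ies_id, i)
  # reverse complement classifies identically
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(whole)))
  expect_identical(classify_read(rc, fx$index)$verdict, "PLUS")
  # plus/minus mixture of one IES is AMBIGUOUS
  mixed <- paste0(probes$minus_probe[1], probes$plus_left_probe[1])
  expect_identical(classify_read(mixed, fx$index)$verdict, "AMBIGUOUS")
  # cross-IES mixture is AMBIGUOUS
  cross <- paste0(probes$plus_left_probe[1], probes$plus_left_probe[2])
  expect_identical(classify_read(cross, fx$index)$verdict, "AMBIGUOUS")
  # short and foreign reads are NONE
  expect_identical(classify_read("ACGTACGT", fx$index)$verdict, "NONE")
})

test_that("per-read verdicts are exhaustive and counts monotone", {
  fx <- balanced_fixture(seed = 111)
  idx <- build_probe_index(fx$catalog$annotations, fx$catalog$mac,
                           fx$catalog$mac_plus_ies, k = fx$k)
  counts <- count_reads(fx$sim$reads, idx)
  expect_identical(
    sum(counts$n_plus) + sum(counts$n_minus) +
      attr(counts, "n_ambiguous") + attr(counts, "n_none"),
    nrow(fx$sim$reads)
  )
  # monotonicity: adding reads never decreases any count
  half <- count_reads(fx$sim$reads[1:400, ], idx)
  expect_true(all(counts$n_plus >= half$n_plus))
  expect_true(all(counts$n_minus >= half$n_minus))
  # strand symmetry: reverse-complementing every read changes nothing
  flipped <- fx$sim$reads
  flipped$sequence <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(flipped$sequence)))
  expect_identical(count_reads(flipped, idx)[, c("n_plus", "n_minus")],
                   counts[, c("n_plus", "n_minus")])
})

test_that("background-only libraries produce zero counts", {
  fx <- make_index_fixture()
  bg <- simulate_genome(1, 5000, seed = 103)
  reads <- substring(as.character(bg)[[1]], seq(1, 4900, 50),
                     seq(1, 4900, 50) + 99)
  counts <- count_reads(stats::setNames(reads, sprintf("b%03d",
                                                       seq_along(reads))),
                        fx$index)
  expect_identical(sum(counts$n_plus) + sum(counts$n_minus), 0L)
})

test_that("counts match a brute-force probe scan on a small library", {
  fx <- balanced_fixture(n_ies = 15, coverage = 15, seed = 121)
  ann <- fx$catalog$annotations
  idx <- build_probe_index(ann, fx$catalog$mac, fx$catalog$mac_plus_ies,
                           k = fx$k)
  counts <- count_reads(fx$sim$reads, idx)
  probes <- make_probes(fx$catalog$mac, fx$catalog$mac_plus_ies, ann,
                        k = fx$k)
  oracle <- brute_force_counts(fx$sim$reads$sequence, probes)
  expect_identical(counts$n_plus, oracle$n_plus)
  expect_identical(counts$n_minus, oracle$n_minus)
})

test_that("paired fragments contribute at most one count per IES", {
  fx <- make_index_fixture()
  probes <- make_probes(fx$catalog$mac, fx$catalog$mac_plus_ies,
                        fx$catalog$annotations, k = 5)
  r1 <- paste0("GG", probes$plus_left_probe[1], "TT")
  r2 <- paste0("AA", probes$plus_right_probe[1], "CC")
  reads <- stats::setNames(c(r1, r2), c("frag1/1", "frag1/2"))
  counts <- count_reads(reads, fx$index)
  expect_identical(counts$n_plus[1], 1L)
  # distinct fragments count separately
  reads2 <- stats::setNames(c(r1, r2), c("fragA", "fragB"))
  counts2 <- count_reads(reads2, fx$index)
  expect_identical(counts2$n_plus[1], 2L)
})

test_that("alignment-based counting applies the MAPQ and span rules", {
  mac <- as_genome(c(s1 = paste0(strrep("A", 20), "CCGGTACCGG",
                                 strrep("G", 20))))
  # junction TA at 25-26
  ann <- tibble::tibble(ies_id = "i1", scaffold = "s1", junction_pos = 25L,
                        sequence = "TACGTCGTA")
  sam <- withr::local_tempfile(fileext = ".sam")
  rec <- function(qname, pos, mapq, cigar = "50M", flag = 0) {
    sprintf("%s\t%d\ts1\t%d\t%d\t%s\t*\t0\t0\t%s\t%s", qname, flag, pos,
            mapq, cigar, strrep("A", 50), strrep("I", 50))
  }
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:s1\tLN:50",
               rec("spans", 1, 37),
               rec("mapq0", 1, 0),
               rec("short_overhang", 24, 37, cigar = "10M40S")), sam)
  counts <- count_from_alignments(ann, k = 5, sam_mac = sam)
  expect_identical(counts$n_minus, 1L)  # only the MAPQ-37 spanning read
  expect_identical(counts$n_plus, 0L)
  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:other\tLN:50", rec("r", 1, 37)), bad)
  expect_error(suppressWarnings(count_from_alignments(ann, k = 5,
                                                      sam_mac = bad)),
               "lacks annotation scaffold")
})

test_that("alignment-based counts agree with probe counts on clean reads", {
  fx <- balanced_fixture(seed = 17)  # ~900 reads, specific probes at k = 8
  ann <- fx$catalog$annotations
  idx <- build_probe_index(ann, fx$catalog$mac, fx$catalog$mac_plus_ies,
                           k = fx$k)
  probe_counts <- count_reads(fx$sim$reads, idx)
  sam_mac <- withr::local_tempfile(fileext = ".sam")
  sam_gl <- withr::local_tempfile(fileext = ".sam")
  write_reads_sam(fx$sim$reads, fx$catalog$mac, "mac", sam_mac)
  write_reads_sam(fx$sim$reads, fx$catalog$mac_plus_ies, "mac_plus_ies",
                  sam_gl)
  sam_counts <- count_from_alignments(ann, k = fx$k, sam_mac = sam_mac,
                                      sam_mac_plus_ies = sam_gl)
  expect_identical(sam_counts$n_plus, probe_counts$n_plus)
  expect_identical(sam_counts$n_minus, probe_counts$n_minus)
})
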