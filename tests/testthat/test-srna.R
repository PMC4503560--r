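random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

srna_pools <- function(seed = 201) {
  list(
    target = Biostrings::DNAStringSet(c(t1 = random_seq(400, seed))),
    mac = Biostrings::DNAStringSet(c(m1 = random_seq(3000, seed + 1),
                                     m2 = random_seq(2000, seed + 2))),
    ies = Biostrings::DNAStringSet(c(i1 = random_seq(800, seed + 3),
                                     i2 = random_seq(600, seed + 4))),
    contaminant = Biostrings::DNAStringSet(c(c1 = random_seq(1500, seed + 5)))
  )
}

test_that("length selection keeps the closed 20-30 nt window in order", {
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    sequence = vapply(c(19, 20, 25, 30, 31), function(n) strrep("A", n), "")
  )
  kept <- length_select(reads)
  expect_identical(kept$read_id, c("r2", "r3", "r4"))
  expect_identical(nrow(length_select(reads[0, ])), 0L)
  expect_error(length_select(reads, 30, 20), "min_len")
})

test_that("contaminant subtraction applies the mismatch threshold", {
  ref <- random_seq(500, 211)
  exact <- substr(ref, 100, 124)
  one_mm <- exact; substr(one_mm, 10, 10) <- if (substr(one_mm, 10, 10) == "A") "C" else "A"
  two_mm <- one_mm; substr(two_mm, 20, 20) <- if (substr(two_mm, 20, 20) == "G") "T" else "G"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exact)))
  clean <- random_seq(25, 212)
  reads <- tibble::tibble(read_id = c("exact", "one", "two", "rc", "clean"),
                          sequence = c(exact, one_mm, two_mm, rc, clean))
  kept <- subtract_contaminants(reads, c(contam = ref), max_mismatch = 1)
  expect_identical(kept$read_id, c("two", "clean"))
  expect_error(subtract_contaminants(reads, Biostrings::DNAStringSet()),
               "non-empty")
})

test_that("contaminant removal equals a brute-force Hamming scan", {
  pools <- srna_pools(221)
  mix <- simulate_srna(300, c(target = 0.2, mac = 0.4, ies = 0.2,
                              contaminant = 0.2), pools, seed = 222)
  refs <- as.character(pools$contaminant)
  kept <- subtract_contaminants(mix$reads, pools$contaminant,
                                max_mismatch = 1)
  oracle_hit <- brute_force_contaminant_hits(mix$reads$sequence, refs, 1)
  expect_identical(kept$read_id, mix$reads$read_id[!oracle_hit])
})

test_that("hierarchical assignment follows tier precedence and uniqueness", {
  tier_a <- Biostrings::DNAStringSet(c(a1 = paste0(
    random_seq(100, 231), "ACGTACGTACGTACGTACGTACGT", random_seq(100, 232))))
  shared <- "TTTTGGGGCCCCAAAATTTTGGGG"
  tier_b <- Biostrings::DNAStringSet(c(
    b1 = paste0(random_seq(50, 233), shared, random_seq(50, 234)),
    b2 = paste0(random_seq(50, 235), shared, random_seq(50, 236))
  ))
  tiers <- list(first = tier_a, second = tier_b)
  reads <- tibble::tibble(
    read_id = c("in_a", "in_b_twice", "nowhere"),
    sequence = c("ACGTACGTACGTACGTACGTACGT", shared, random_seq(24, 237))
  )
  prof <- hierarchical_assign(reads, tiers)
  asg <- attr(prof, "assignments")
  expect_identical(asg$category[asg$read_id == "in_a"], "first")
  expect_identical(asg$category[asg$read_id == "in_b_twice"], "nonunique")
  expect_identical(asg$category[asg$read_id == "nowhere"], "unmapped")
  # precedence: a read present in both tiers goes to the first
  both <- paste0(random_seq(30, 238), "ACGTACGTACGTACGTACGTACGT")
  tiers2 <- list(first = tier_a,
                 second = Biostrings::DNAStringSet(c(b = both)))
  r2 <- tibble::tibble(read_id = "x", sequence = "ACGTACGTACGTACGTACGTACGT")
  p2 <- hierarchical_assign(r2, tiers2)
  expect_identical(attr(p2, "assignments")$category, "first")
  expect_error(hierarchical_assign(reads, list(a = tier_a, a = tier_b)),
               "named")
})

test_that("raw category counts partition the input reads", {
  pools <- srna_pools(241)
  mix <- simulate_srna(2000, c(target = 0.1, mac = 0.55, ies = 0.25,
                               contaminant = 0.1), pools, seed = 242)
  prof <- srna_profile(mix$reads,
                       tiers = list(target = pools$target, mac = pools$mac,
                                    ies = pools$ies),
                       contaminants = pools$contaminant)
  survivors <- subtract_contaminants(length_select(mix$reads),
                                     pools$contaminant)
  expect_identical(sum(prof$n_raw) + sum(prof$n_nonunique),
                   nrow(survivors))
  expect_identical(attr(prof, "total_mapped"),
                   sum(prof$n_raw[prof$category != "unmapped"]))
  pm <- prof$per_million[prof$category != "unmapped"]
  expect_equal(sum(pm), 1e6, tolerance = 1e-9)
})

test_that("non-overlapping planted mixtures are recovered exactly", {
  pools <- srna_pools(251)
  mix <- simulate_srna(4000, c(target = 0.1, mac = 0.6, ies = 0.2,
                               contaminant = 0.1), pools, seed = 252)
  prof <- srna_profile(mix$reads,
                       tiers = list(target = pools$target, mac = pools$mac,
                                    ies = pools$ies),
                       contaminants = pools$contaminant)
  truth_counts <- table(mix$truth$category)
  for (tier in c("target", "mac", "ies")) {
    expect_identical(prof$n_raw[prof$category == tier],
                     as.integer(truth_counts[[tier]]))
  }
  expect_identical(prof$n_raw[prof$category == "unmapped"], 0L)
  # filter order is immaterial: both are per-read filters
  reordered <- subtract_contaminants(mix$reads, pools$contaminant)
  reordered <- length_select(reordered)
  standard <- length_select(mix$reads)
  standard <- subtract_contaminants(standard, pools$contaminant)
  expect_identical(standard, reordered)
})

test_that("per-million normalization is invariant under subsampling", {
  pools <- srna_pools(261)
  mix <- simulate_srna(6000, c(target = 0.1, mac = 0.6, ies = 0.2,
                               contaminant = 0.1), pools, seed = 262)
  tiers <- list(target = pools$target, mac = pools$mac, ies = pools$ies)
  full <- srna_profile(mix$reads, tiers, contaminants = pools$contaminant)
  half_reads <- withr::with_seed(263, {
    mix$reads[sample.int(nrow(mix$reads), nrow(mix$reads) / 2), ]
  })
  half <- srna_profile(half_reads, tiers, contaminants = pools$contaminant)
  for (tier in c("target", "mac", "ies")) {
    a <- full$per_million[full$category == tier]
    b <- half$per_million[half$category == tier]
    expect_lt(abs(a - b) / a, 0.15)
  }
})

test_that("a planted IES/MAC enrichment is recovered within sampling error", {
  pools <- srna_pools(271)
  tiers <- list(target = pools$target, mac = pools$mac, ies = pools$ies)
  early <- simulate_srna(20000, c(target = 0.05, mac = 0.8, ies = 0.04,
                                  contaminant = 0.11), pools, seed = 272)
  late <- simulate_srna(20000, c(target = 0.05, mac = 0.6, ies = 0.21,
                                 contaminant = 0.14), pools, seed = 273)
  p_early <- srna_profile(early$reads, tiers,
                          contaminants = pools$contaminant)
  p_late <- srna_profile(late$reads, tiers, contaminants = pools$contaminant)
  ratio <- enrichment_ratio(p_early, p_late)
  # planted: (0.21/0.6) / (0.04/0.8) = 7
  expect_lt(abs(ratio - 7), 0.6)
  expect_equal(enrichment_ratio(p_early, p_early), 1)
  # doubling the late IES count doubles the ratio
  doubled <- p_late
  doubled$per_million[doubled$category == "ies"] <-
    2 * doubled$per_million[doubled$category == "ies"]
  expect_equal(enrichment_ratio(p_early, doubled) / ratio, 2,
               tolerance = 1e-9)
})
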