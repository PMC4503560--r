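test_that("genome simulation is deterministic and honours composition", {
  g1 <- simulate_genome(1, 1000, 0.5, seed = 1)
  g2 <- simulate_genome(1, 1000, 0.5, seed = 1)
  expect_identical(as.character(g1), as.character(g2))
  only_at <- simulate_genome(1, 500, at_fraction = 1, seed = 2)
  expect_false(grepl("[CG]", as.character(only_at)[1]))
  big <- simulate_genome(1, 100000, at_fraction = 0.72, seed = 3)
  freq <- Biostrings::letterFrequency(big, c("A", "T"))
  expect_lt(abs(sum(freq) / 100000 - 0.72), 0.02)
})

test_that("catalog placement respects spacing, margins and TA boundaries", {
  g <- simulate_genome(2, 30000, seed = 11)
  cat0 <- simulate_ies_catalog(g, 40, min_spacing = 250L, edge_margin = 150L,
                               seed = 12)
  ann <- cat0$annotations
  expect_identical(nrow(ann), 40L)
  gaps <- ann |>
    dplyr::group_by(scaffold) |>
    dplyr::summarise(min_gap = min(diff(junction_pos), Inf))
  expect_true(all(gaps$min_gap >= 250))
  expect_true(all(ann$junction_pos >= 150))
  # validator re-run passes, i.e. TA boundary invariants hold
  expect_silent(validate_ies_annotations(ann, cat0$mac))
  expect_error(simulate_ies_catalog(simulate_genome(1, 300, seed = 1), 50),
               "longer genome")
  empty <- simulate_ies_catalog(g, 0, seed = 1)
  expect_identical(nrow(empty$annotations), 0L)
  expect_identical(as.character(empty$mac_plus_ies), as.character(g))
})

test_that("sampled IES lengths follow the configured distribution", {
  sampler <- function(n) sample(c(30L, 50L, 70L), n, replace = TRUE,
                                prob = c(0.5, 0.3, 0.2))
  g <- simulate_genome(4, 100000, seed = 21)
  cat0 <- simulate_ies_catalog(g, 1000, length_sampler = sampler,
                               min_spacing = 300L, seed = 22)
  obs <- table(factor(cat0$annotations$length, levels = c(30, 50, 70)))
  chi <- suppressWarnings(
    stats::chisq.test(obs, p = c(0.5, 0.3, 0.2))
  )
  expect_gt(chi$p.value, 0.001)
})

test_that("degenerate retention mixtures produce pure read sets", {
  g <- simulate_genome(1, 15000, seed = 31)
  cat0 <- simulate_ies_catalog(g, 10, seed = 32)
  all0 <- simulate_excision_reads(cat0$mac, cat0$mac_plus_ies,
                                  cat0$annotations,
                                  retention_truth(cat0$annotations, 0, 40),
                                  background_fraction = 0, seed = 33)
  expect_identical(sum(all0$reads$type == "plus"), 0L)
  all1 <- simulate_excision_reads(cat0$mac, cat0$mac_plus_ies,
                                  cat0$annotations,
                                  retention_truth(cat0$annotations, 1, 40),
                                  background_fraction = 0, seed = 34)
  expect_identical(sum(all1$reads$type == "minus"), 0L)
})

test_that("per-IES IES+ fractions concentrate around r", {
  g <- simulate_genome(3, 60000, seed = 41)
  cat0 <- simulate_ies_catalog(g, 120, seed = 42)
  sim <- simulate_excision_reads(cat0$mac, cat0$mac_plus_ies,
                                 cat0$annotations,
                                 retention_truth(cat0$annotations, 0.3, 200),
                                 background_fraction = 0, seed = 43)
  frac <- sim$reads |>
    dplyr::filter(type != "background") |>
    dplyr::group_by(ies_id) |>
    dplyr::summarise(n = dplyr::n(), f = mean(type == "plus"))
  within3sd <- abs(frac$f - 0.3) <= 3 * sqrt(0.3 * 0.7 / frac$n)
  expect_gte(mean(within3sd), 0.97)
})

test_that("simulated reads and truth tables are reproducible byte for byte", {
  g <- simulate_genome(1, 10000, seed = 51)
  cat0 <- simulate_ies_catalog(g, 8, seed = 52)
  truth <- retention_truth(cat0$annotations, 0.5, 20)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_excision_reads(cat0$mac, cat0$mac_plus_ies, cat0$annotations,
                          truth, seed = 53, fastq = f1)
  simulate_excision_reads(cat0$mac, cat0$mac_plus_ies, cat0$annotations,
                          truth, seed = 53, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0)
})

test_that("read ids encode the simulated origin", {
  fx <- balanced_fixture(n_ies = 5, coverage = 10, seed = 61)
  ids <- fx$sim$reads$read_id
  expect_true(all(grepl("^sim[0-9]+:(plus|minus|background):", ids)))
  parsed_type <- sub("^sim[0-9]+:([a-z]+):.*$", "\\1", ids)
  expect_identical(parsed_type, fx$sim$reads$type)
})

test_that("sRNA mixtures honour proportions, lengths and substring origin", {
  pools <- list(
    target = Biostrings::DNAStringSet(c(t1 = paste(
      sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))),
    mac = simulate_genome(1, 2000, at_fraction = 0.5, seed = 71),
    ies = Biostrings::DNAStringSet(c(i1 = paste(
      sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""))),
    contaminant = Biostrings::DNAStringSet(c(c1 = paste(
      sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")))
  )
  mix <- simulate_srna(10000, c(target = 0.1, mac = 0.6, ies = 0.2,
                                contaminant = 0.1), pools, seed = 72)
  lens <- nchar(mix$reads$sequence)
  expect_true(all(lens >= 20 & lens <= 30))
  counts <- table(mix$reads$category)
  expected <- c(contaminant = 1000, ies = 2000, mac = 6000, target = 1000)
  for (nm in names(expected)) {
    se <- sqrt(expected[[nm]] * (1 - expected[[nm]] / 10000))
    expect_lt(abs(counts[[nm]] - expected[[nm]]), 4 * se)
  }
  # reads are exact substrings of their source pool (on one strand)
  sub <- mix$reads[sample.int(nrow(mix$reads), 100), ]
  ok <- vapply(seq_len(nrow(sub)), function(i) {
    pool <- pools[[sub$category[i]]]
    s <- sub$sequence[i]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    any(grepl(s, as.character(pool), fixed = TRUE)) ||
      any(grepl(rc, as.character(pool), fixed = TRUE))
  }, logical(1))
  expect_true(all(ok))
  # single-category mixture
  only_mac <- simulate_srna(200, c(target = 0, mac = 1, ies = 0,
                                   contaminant = 0), pools, seed = 73)
  expect_true(all(only_mac$reads$category == "mac"))
})

test_that("planted contig coverage designs sit on the right side of 2 RPKM", {
  design <- list(
    control = c(rep(TRUE, 10), rep(FALSE, 10)),
    knockdown = rep(TRUE, 20)
  )
  cov <- simulate_contig_coverage(20, design, seed = 81)
  cc <- contig_coverage(cov)
  expect_identical(cc$covered, cc$covered_true)
  # all-uncovered design
  none <- simulate_contig_coverage(5, list(d = rep(FALSE, 5)), seed = 82)
  expect_identical(covered_set(none), character(0))
})
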