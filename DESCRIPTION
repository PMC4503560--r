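Package: iescall
Title: Retention Scoring and Small-RNA Profiling for Programmed DNA
    Elimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies programmed DNA elimination in ciliates from
    junction-spanning sequencing reads. Internal Eliminated Sequences
    (IESs) are scored for retention in a developing somatic genome by
    counting reads that support the unexcised (IES+) versus excised
    (IES-) form of each excision junction, and significantly retained
    IESs are called against a control sample with an exact binomial test
    anchored on the Clopper-Pearson interval of the control retention
    score, with Benjamini-Hochberg correction. Companion stages profile
    20-30 nt small-RNA populations by hierarchical exact mapping and
    estimate germline-restricted sequence complexity from per-contig
    RPKM coverage. A seeded synthetic-data module generates genomes,
    IES catalogs, read sets and coverage profiles with known truth so
    that every stage can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
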