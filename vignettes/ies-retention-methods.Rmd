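---
title: "Scoring IES retention and profiling developmental small RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring IES retention and profiling developmental small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iescall)
library(dplyr)
```

## The biological problem

Ciliates such as *Paramecium tetraurelia* carry two kinds of nuclei: a
germline micronucleus (MIC) and a somatic macronucleus (MAC). At each
sexual cycle a new MAC develops from a copy of the germline genome and is
massively rearranged: repeated elements are eliminated imprecisely, and
tens of thousands of short, single-copy Internal Eliminated Sequences
(IESs) are excised precisely. Every IES is bounded by two TA
dinucleotides, one of which is retained in the somatic sequence as the
excision junction. When a factor required for excision is silenced, some
IESs stay in the developing somatic genome; deep sequencing of that
genome then shows, for each IES, a mixture of reads supporting the
unexcised form (IES+) and reads supporting the excised junction (IES-).

`iescall` implements the quantitative side of such experiments:

1. a **reference model** for MAC genomes, IES catalogs and the
   germline-like "MAC+IES" reference obtained by reinserting every IES;
2. **junction counting** of IES+ and IES- reads, either by exact probe
   matching or from SAM alignments;
3. **retention statistics**: per-IES retention scores and a significance
   procedure that calls IESs retained relative to a control sample;
4. a **small-RNA profiling** stage (length selection, contaminant
   subtraction, hierarchical exact-unique mapping, per-million
   normalization and an IES/MAC enrichment ratio);
5. a **coverage-complexity** stage classifying contigs of a
   germline-enriched assembly as covered or not per dataset, and
   measuring the complexity private to a knockdown;
6. a seeded **synthetic-data module** that generates genomes, catalogs,
   reads and coverage profiles with known truth, so every stage can be
   exercised end to end and its calibration verified.

## The retention model

For one IES let $n^+$ and $n^-$ be the numbers of reads supporting the
unexcised and excised form. The retention score is

$$\mathrm{RS} = \frac{n^+}{n^+ + n^-},$$

0 for complete excision and 1 for complete retention; it is undefined
(`NA`) when no junction-spanning reads were observed.

To decide whether an IES is *significantly* retained in an experiment
relative to a control, the caller:

1. computes the exact (Clopper-Pearson) two-sided confidence interval of
   the control RS at confidence `alpha` (default 0.95), by beta-quantile
   inversion of the binomial CDF;
2. tests the experimental IES+ count against the **upper bound** of that
   interval with a one-sided binomial tail test,
   $p = P\{X \ge n^+_{\text{exp}}\}$ for
   $X \sim \mathrm{Bin}(n^+_{\text{exp}} + n^-_{\text{exp}},\ \mathrm{CI}_{\text{high}})$;
3. adjusts the p-values across all tested IESs with the
   Benjamini–Hochberg step-up procedure;
4. calls an IES retained when the adjusted p-value is strictly below the
   threshold (default 0.05).

Using the interval's upper bound rather than the control point estimate
makes the test conservative: an experiment must exceed even an
optimistic reading of the control before an IES is called. Two
consequences are intended and documented behaviour: a control that is
itself fully retained ($x = n$, $\mathrm{CI}_{\text{high}} = 1$) can
never yield a call, and an experiment with zero IES+ reads always has
$p = 1$. IESs lacking coverage in either sample are excluded from
testing and never enter the BH family (`min_coverage`, default 1,
controls the cutoff; the default imposes only a non-zero denominator).

```{r stats-example}
clopper_pearson(0, 200)
binomial_tail_pvalue(40, 100, clopper_pearson(0, 200)$high)
```

## Counting rules

Reads are counted **only at IES ends**, so that long and short IESs are
measured on the same footing. Each IES defines three probes of equal
width $2k + 2$, where `k` (the *overhang*, default 5) is the number of
anchoring bases required on each side of the relevant TA:

* the junction probe: $k$ MAC bases, the junction TA, $k$ MAC bases —
  evidence for the excised form;
* two boundary probes: $k$ flanking bases plus the first (or last)
  $k + 2$ IES bases — evidence for the unexcised form.

A read is classified by exact substring matching (either strand) of the
probe dictionary: `PLUS` or `MINUS` if it hits probes of exactly one
IES and one kind (a read spanning an entire short IES hits both boundary
probes of that IES and still counts once); `AMBIGUOUS` if it hits a
probe string shared by two IESs, probes of two different IESs, or both
junction and boundary evidence; `NONE` otherwise. Matching is exact by
design — the counts feed an exact binomial test, and error tolerance is
a property of the library, not of the matcher. For paired libraries a
fragment contributes at most one count per IES.

The same rules are available on alignments: a primary, non-supplementary
SAM record with mapping quality at least 1 counts when its aligned
segment covers the junction TA (MAC reference) or either terminal TA of
the IES (MAC+IES reference) with at least `k` aligned bases on each
side — precisely the span of the corresponding probe, so on error-free
reads the two modes agree read for read. The package consumes SAM text
via the standard Bioconductor readers; it does not implement an aligner.

Two practical caveats, both surfaced by the index builder rather than
silently absorbed: an IES within `k` bases of a scaffold end has no
probes and is excluded from counting with a warning, and an IES whose
three probes are not three distinct strings at the chosen `k` (possible
for tiny toy IESs) is flagged "uncountable" because classification would
be ambiguous by construction. Probes containing `N` never match any
read.

The default `k = 5` is a compromise: small enough that nearly every
junction-spanning read retains both anchors, large enough to anchor the
invariant TA in its local context. With 12-bp probes, exact matching is
specific in genome-scale references, but in *small random fixtures* a
12-mer can recur by chance: in an i.i.d. AT-rich toy genome roughly one
read in twelve picks up a coincidental probe hit, which both discards
informative reads as ambiguous and — worse — plants spurious IES+
counts in the control, inflating its confidence interval and eroding
power. The anchoring width is therefore chosen to match the reference
scale: tests that assert exact agreement between counting modes use
GC-balanced fixtures at `k = 8` (18-bp probes), and the end-to-end
calibration runs use `k = 12` (26-bp probes), at which the expected
number of chance matches across the whole fixture is far below one
read. This is a property of fixture scale, not of the counting rules;
on genome-scale references the default `k = 5` retains its intended
behaviour.

## What the generators emulate

The synthetic-data module is the package's study design, not a test
fixture dial; its defaults state the conditions under which the
calibration claims hold.

* **Genomes** are i.i.d. base sequences with configurable AT content
  (default 0.72, matching the AT-rich *Paramecium* somatic genome).
* **IES catalogs** plant TA junctions at least `min_spacing` apart
  (default 300 bp) and away from scaffold ends, with lengths drawn by
  default from the field's periodic size distribution: a dominant
  shortest class at 26–32 bp, then peaks roughly every 10 bp with
  decaying weight. IES interiors are more AT-rich (default 0.8) than
  the background.
* **DNA-seq libraries**: per IES, a Poisson number of junction-spanning
  reads (mean `coverage`), each IES+ with probability equal to the true
  retention fraction $r$, with uniform start offsets among those leaving
  `k` anchoring bases; defaults copy common practice for such libraries
  (read length 101 nt). Background reads from non-junction regions are
  added (30% of the library by default) to exercise the `NONE` path.
  Base qualities are fixed at `"I"` since the analysis never uses them,
  and sequencing errors default to off (an optional uniform substitution
  rate exists to stress exact matching). `simulate_junction_counts()`
  exposes the same model at the counts level — Poisson coverage,
  binomial IES+ — which is the exact conditional distribution of
  counting an error-free library, and is used for statistical
  calibration at scales where materializing reads adds nothing.
* **Small-RNA mixtures** draw reads of 20–30 nt (length distribution
  peaked at 25 nt) as exact substrings of category pools
  (silencing-target, MAC, IES, contaminant) with recorded truth.
* **Contig coverage** plants covered/uncovered designs with RPKM targets
  in guard bands (5–50 versus 0–1.5) so integer rounding can never cross
  the 2-RPKM threshold.

All generators are pure functions of their configuration and seed;
byte-identical outputs across runs are asserted in the tests. Read ids
encode the simulated origin so that oracle checks can compare verdicts
with truth.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: mapping ambiguity from paralogy and repeats
(real "unambiguous alignment" filtering is approximated by the
probe-uniqueness rule and a MAPQ threshold), copy-number differences
between old-MAC fragments and the developing MAC in a nuclear
preparation, sequencing error profiles, adapter artefacts, and any
correlation structure between neighbouring IESs.

## Small-RNA stage choices

The profiling order is fixed: length selection (closed window, default
20–30 nt), contaminant subtraction (Hamming distance at most 1 to any
contaminant reference, either strand), then hierarchical assignment.
The first two steps are per-read filters, so their order is immaterial
(asserted in tests). Assignment walks the tiers in order — silencing
target, rest of MAC, IESs — and takes the first tier with an exact
match at *exactly one location* across that tier's sequences
(occurrences counted on both strands with overlaps allowed). Reads
matching one tier at several locations are discarded as non-unique and,
by default, are not offered to later tiers: they did match that tier,
just not uniquely. The alternative reading — uniqueness judged only
within the whole reference — is available via `cascade_nonunique`.
Normalization divides by the total of reads assigned to any tier (the
reads mapped to an organism reference), times $10^6$.

## Complexity stage choices

A contig counts as covered when its RPKM (reads per kb of contig per
million mapped reads) is strictly above 2 and its length strictly above
1 kb. The complexity private to a dataset is the summed length of
contigs covered by it but not by the control; the headline quantity is
the fraction of the reference-private (germline-restricted) complexity
that a knockdown also covers. Quartile summaries use type-7 quantiles
(linear interpolation between order statistics) with left-closed bins —
the convention is locked in a test against a hand computation
(`quantile(1:8, .25) = 2.75`). Group-to-group score comparisons use the
two-sided Mann–Whitney test, exact by enumeration when both groups have
at most 8 tie-free observations and the normal approximation with tie
and continuity correction otherwise, with BH correction across the
sequence of comparisons — mirroring the retention caller's policy.

## Pipeline and reproducibility

`run_pipeline()` wires the stages together from a single configuration
(a named list or YAML file): simulate (optional) → count → call →
compare. One top-level seed is expanded per stage by a fixed offset
rule; a manifest records the configuration hash, package version, input
checksums and per-stage row counts. Two runs from the same
configuration produce byte-identical tables. The package deliberately
ships no shell front-end: it is an analysis library, and the
configuration-driven `run_pipeline()` plus the exported stage functions
are its interface.

## Calibration results computed by the test-suite and acceptance script

The claims below are exactly those recomputed by `tests/testthat/` and
`scripts/acceptance.R`; the vignette states them without numbers that
the code does not itself produce.

* Clopper-Pearson intervals agree with bisection inversion of the
  binomial CDF to $10^{-6}$ for all $x, n \le 30$; tail p-values agree
  with direct pmf summation to $10^{-12}$; BH agrees with hand step-up
  computations.
* Probe counting equals a brute-force scan of every probe in every read
  on a small library, and equals alignment-mode counting on the same
  error-free reads.
* Insertion and excision are exact inverses on seeded random genomes.
* With 2,000 IESs at coverage 100 and true retention uniform on [0, 1],
  the exact 95% interval around the measured RS covers the truth for
  92–98% of IESs, and the mean absolute RS error stays below 1.5 times
  the mean binomial standard error.
* Under the null (both samples fully excised) the retained fraction
  stays at or below 0.05 across five seeds; with a well-covered control
  and an experiment at $r = 0.4$, coverage 30, at least 90% of IESs are
  called.
* An end-to-end run with 300 IESs — half fully excised, half with true
  retention uniform on [0.1, 0.7] — returns a retained fraction within
  5 percentage points of 50%, with retained scores spread over the
  simulated range rather than piled at zero. The problem sizes here
  (60-kb scaffolds, coverage 100) were chosen as the smallest at which
  the binomial machinery, not sampling noise, dominates the outcome.
* Planted small-RNA mixtures with non-overlapping sources are recovered
  exactly; normalization is invariant under two-fold subsampling within
  sampling error; a planted 7-fold IES/MAC enrichment is recovered
  within multinomial error.
* Planted contig-coverage designs are recovered exactly, and a fixture
  built so that 64% of the germline-restricted complexity depends on the
  knockdown returns exactly 64%.

## Known limitations

* Exact probe matching does not tolerate sequencing errors; a read with
  a substitution inside the probe window is silently `NONE`. On real
  libraries the alignment-based mode is the appropriate entry point.
* The uniqueness rules are exact-string surrogates for "unambiguous
  alignment"; they do not model mismatch-tolerant multi-mapping.
* The complexity stage assumes the contig panel and library sizes are
  given; it does not assemble contigs or recompute mapping.
* The caller tests over-retention only; under-retention (an IES excised
  *better* upon knockdown) is out of scope, as are shrinkage or
  empirical-Bayes variants of the score.
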