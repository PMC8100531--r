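---
title: "Comparative piRNA analysis of fresh and frozen-thawed sperm: methods"
author: "cryopiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative piRNA analysis of fresh and frozen-thawed sperm: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryopiR)
```

## The scientific problem

Sperm cryotolerance differs sharply across species: giant panda sperm
survives repeated freeze-thaw cycles while boar sperm is notoriously
cold-sensitive. One molecular window onto this difference is the PIWI-
interacting RNA (piRNA) complement of sperm -- germline small non-coding
RNAs, typically 24-32 nt with a strong 5'-uridine (1U) bias, transcribed
from discrete genomic clusters. Comparing piRNA expression between fresh
and frozen-thawed sperm of a freeze-tolerant and a freeze-sensitive
species, and asking which differentially expressed (DE) piRNAs are shared
between the species and which are species-unique, gives a concrete,
sequence-level readout of cryoinjury.

`cryopiR` implements that comparison end to end as a testable pipeline:

1. **Read cleaning** -- 3' adapter trimming, mean-quality and poly-N
   filtering, and a two-stage length filter.
2. **ncRNA removal** -- reads matching annotated rRNA/tRNA/snRNA/snoRNA/
   repeat sequences are discarded before mapping.
3. **Genome mapping** -- exact end-to-end placement with a configurable
   substitution budget, both strands, all loci reported.
4. **Cluster detection** -- density-based piRNA cluster calls from mapped
   5' ends.
5. **Quantification and differential expression** -- sequence-level TPM, a
   no-replicate negative-binomial exact test, Benjamini-Hochberg
   adjustment.
6. **Cross-species homology partition** -- the 5'-anchored pairing rule
   that splits each species' DE piRNAs into common and unique sets.
7. **Target prediction and GO/KEGG over-representation.**

Every stage is driven by a synthetic-data generator with planted truth, so
each claim the pipeline makes can be checked against a known answer
without any external download.

## The synthetic-data generator

`sim_config()` + `generate_genome()` + `generate_annotations()` +
`simulate_libraries()` emulate the design of a two-species sperm
cryopreservation experiment: for each species a single pooled library per
condition (fresh, frozen-thawed) -- ejaculates are pooled before library
construction, so the downstream test must work at n = 1 vs n = 1.

What is planted, and why:

* **Clusters.** Each toy genome (default two chromosomes of 100 kb)
  carries eight disjoint clusters of 2 kb, each with 25 distinct piRNA
  loci on a jittered grid (spacing at least 40 nt so loci never overlap
  and later sequence edits stay local). Lengths follow a unimodal
  distribution over 24-32 nt peaking at 29-30 nt, the canonical mammalian
  sperm piRNA range.
* **5'-U bias.** Each planted locus starts with T (the DNA face of U)
  with probability 0.8 -- the canonical primary piRNA signature, and the
  fingerprint the cluster caller tests.
* **Homologs.** A configurable number of species-B loci (default 10) are
  overwritten with copies of species-A piRNAs, optionally carrying one
  substitution at position 19 or later, so the cross-species pairing rule
  has planted positives. At generation time the truth list is verified by
  brute force over every cross-species pair of planted sequences.
* **Expression.** Per-piRNA negative-binomial means are uniform on
  20-200 counts with dispersion 0.1 (typical bulk small RNA-seq
  overdispersion); a `de_fraction` of 0.1 receives a planted log2 fold
  change of +/-3. Per-library means are rescaled so the signal portion of
  each library is close to `reads_per_library`; this mimics fixed
  sequencing depth and leaves fold changes intact after size-factor
  normalisation.
* **Contamination.** A `contam_fraction` (default 0.1) of reads is split
  evenly among five classes: ncRNA fragments (survive the length/quality
  filters, die at the ncRNA filter), adapter dimers (fail stage-1
  length), poly-N reads, genome fragments of out-of-window lengths
  (exercise both length stages), and well-formed fragments with mean
  Phred < 20 (exercise the quality filter).
* **Geometry.** Reads are insert + 3' adapter truncated at 50 nt, with
  Phred+33 qualities; this is the standard small RNA library layout and
  makes adapter trimming non-optional.

What the generator does **not** emulate: position-dependent sequencing
error, isomiR/fragment heterogeneity, species-specific genome content and
repeat structure, and multi-mapping at realistic rates (random toy
genomes make most 24-32-mers unique). Passing tests therefore demonstrate
the correctness of the algorithms under the planted model, not
performance on real libraries.

All randomness descends from the single `seed` field; generation,
annotation and library simulation use fixed offsets of it, so identical
configurations reproduce byte-identical outputs.

## Read cleaning

The raw-to-clean accounting follows the two length statements of sperm
small RNA work: stage 1 keeps 18-34 nt ("clean reads"), stage 2 keeps the
piRNA range 24-32 nt (the set used for clustering and differential
expression). Both windows are inclusive and configurable. "Low quality"
is mean Phred < 20 and "poly-N" is more than 10% ambiguous bases --
common sRNA-seq conventions, both configurable. Filters apply in a fixed
order (quality, poly-N, stage-1 length, stage-2 length) so every read
lands in exactly one failure bin and the statistics are conserved and
order-independent; the stage-2 filter precedes mapping.

Adapter trimming removes the longest read suffix that exactly matches an
adapter prefix of at least `min_overlap` (default 5) nt. Exact
suffix-prefix matching is deliberate: the simulator ligates adapters
without error, and mismatched-adapter recovery is out of scope.

## Mapping and the mapped ratio

`map_reads()` reports **all** loci where a sequence aligns end-to-end
with at most `max_mismatch` substitutions (default 0, no indels) on
either strand, built on `Biostrings::matchPattern()` with candidate hits
re-verified by direct character comparison. The test suite holds this
against an independent naive all-windows scan at 0 and 1 mismatches.

The mapped ratio is reported relative to **clean reads**. On the
published sequencing-overview numbers for the freeze-tolerant species
this convention reproduces both printed percentages (85,586/519,311 =
16.48%; 325,288/4,488,163 = 7.2% at one decimal); the freeze-sensitive
species' rows are not internally consistent under any single denominator
and are not used as a check.

Multi-mapping sequences stay in the analysis with all their loci; each
locus contributes `count / n_loci` reads downstream, avoiding double
counting without discarding cluster signal.

## Cluster detection

`detect_clusters()` captures the density logic of proTRAC-style callers
without cloning a probabilistic model: hit 5' ends are merged into
maximal runs with gaps <= `max_gap` (1 kb), and a run is a cluster iff
its span is >= `min_span` (1 kb), it has >= `min_members` (10) distinct
member sequences, >= 30% of members begin with 5' U, and >= 75% of
members are 24-32 nt. Defaults were chosen once, to match the planted
cluster geometry (25 loci over 2 kb) with a wide margin, and are all
configurable. Raising `min_members` can only reduce the number of calls,
a property the tests assert.

## Quantification

piRNA identity is the distinct read sequence, not a genomic locus --
consistent with reporting "piRNAs expressed" as sequence tallies. TPM is
the per-library count scaled to one million. Length normalisation is
off by default (piRNA lengths vary only 24-32 nt, a < 1.4-fold range that
would merely add noise); `per_kilobase = TRUE` restores classical TPM.
Either way the per-library TPM sums to exactly 10^6.

## Differential expression without replicates

With one pooled library per condition there is no within-condition
replication, so:

* **Normalisation** is median-of-ratios (the estimator of the cited DE
  package), cross-checked in the tests against an independent
  implementation.
* **Dispersion** is estimated blind: both libraries are treated as a
  pooled pseudo-group. The per-feature two-value method-of-moments
  estimate is, under the null, a scaled chi-square with one degree of
  freedom; the parametric trend `dispersion = a0 + a1/mean` is therefore
  fitted by median (LAD) regression of the unfloored raw values on
  `1/mean` and rescaled by the chi-square(1) median (0.4549). The median
  regression is what makes the blind fit usable: genuinely differential
  features have raw blind dispersions near
  `2 * ((2^lfc - 1) / (2^lfc + 1))^2` (about 1.2 at |lfc| = 3)
  regardless of depth, and a mean-based fit is dragged upward by them
  while the median is not.
* **Sharing mode.** The working dispersion is the fitted trend value
  (`sharing_mode = "fit-only"`). Taking the per-feature maximum of raw
  and fitted is available but documented as exploratory only: in the
  blind setting the raw value of a true positive contains its own signal,
  so "maximum" makes strong DE features *less* significant the larger
  their effect, and no feature can pass stringent thresholds. Fit-only is
  also what the cited package does when it detects a no-replicate design.
* **The test** is a two-sided exact negative-binomial test conditioning
  on the per-feature total of the rounded normalised counts: under equal
  means, the p-value is the probability mass of all splits no more
  probable than the observed one. It is checked against a direct
  enumeration oracle, returns 1 for equal or empty splits, and is
  symmetric under label swap.
* **Multiple testing** is Benjamini-Hochberg; calls use the strict
  thresholds `padj < 0.01` and `|log2FC| > 1`, with the fold change
  computed on normalised counts with a pseudocount of 1 per side so zero
  counts stay finite.

Calibration and power are both exercised as acceptance properties: on
null simulations (2,000 features, 20 seeds, dispersion 0.1) the fraction
of `padj < 0.01` calls stays at or below 0.01, and on a high-signal
simulation (8-fold effects, means 100-400, dispersion 0.01) the planted
40 up / 10 down features are recovered exactly. The heatmap helper
transforms TPM as `log10(TPM + 1)` and clusters rows with Euclidean
distance and complete linkage, matching a naive agglomeration oracle.

## The cross-species homology rule

Two piRNAs from different species pair iff, anchored at the 5' end,
positions 1-18 are identical and at most one mismatch occurs from
position 19 through the end of the shorter sequence; the 3' overhang of
the longer sequence is ignored. Design choices where the rule's prose is
silent:

* Comparison over the shorter length with free overhang -- piRNA 5' ends
  are the conserved, PIWI-anchored feature, and the rule names positions
  from base 1.
* "After the 19th base" is read as "at positions >= 19"; the constructed
  acceptance instance uses the same reading, so the reported set
  arithmetic does not depend on it.
* Sequences shorter than 19 nt cannot satisfy the rule.
* U and T are interchangeable on input.
* Pairing is membership-based by default: a DE piRNA is "common" if any
  partner matches, matching how common piRNAs are counted per species; a
  strict one-to-one mode (greedy best-score assignment) is available.

`best_pair()` resolves ties deterministically: fewest mismatches, then
longest overlap, then lexicographically smallest partner.

`make_homology_instance()` rebuilds the published set arithmetic as a
constructed instance: 1,160 and 384 distinct sequences with exactly 28
planted cross-species pairs satisfying the rule and no accidental ones
(18-mer prefixes are kept collision-free, which random sequences achieve
with overwhelming probability, and the construction is verified before
use). Partitioning it yields 1,132 and 356 species-unique DE piRNAs.

## Target prediction and enrichment

The published target-prediction protocol names only an aligner and
annotation databases, so the package implements a transparent,
configurable stand-in: a piRNA targets a transcript iff the reverse
complement of its seed (piRNA positions 2-11) occurs exactly in the
transcript and the full-length antisense extension carries at most 2
substitutions. The antisense requirement is asserted (a sense-strand
occurrence is not a target), and the implementation is tested against an
exhaustive per-offset scan.

Enrichment is the hypergeometric upper tail per term,
`P(X >= k)` with universe size `N`, term size `K` and target set size
`n`, BH-adjusted within GO and within KEGG separately. The universe is
the set of annotated transcripts. Ranking is ascending adjusted p, ties
broken by descending `k`, then term id.

## Orchestration

`run_pipeline()` executes the stages on an in-memory state;
`run_stage()` exposes them individually and refuses to run a stage whose
upstream output is missing, naming the stage to run first. With an
output directory, every stage writes TSV/BED and the report is written
as JSON; every number in the report is recomputable from the written
tables, and reruns under the same seed are byte-identical.

## Problem sizes and numerical choices

The shipped defaults and the sizes used by the test-suite properties --
toy genomes of 30-100 kb, libraries of 3,000-20,000 reads, 100-2,000
expression features, homology sets up to a few hundred sequences (and
the full 1,160 x 384 constructed instance) -- were chosen as the smallest
scales at which every planted structure is unambiguous: clusters are
well-separated relative to `max_gap`, planted effects are far from the
decision thresholds, and brute-force oracles remain exhaustive.
Degenerate inputs are defined, not special-cased: empty read sets give
zeroed statistics, empty hit sets give zero clusters, an all-zero count
pair gives p = 1, fewer than two heatmap rows give the identity order,
and an empty DE set propagates to an all-zero report.

## Known limitations

* The exact test enumerates all splits of a feature's total; it is meant
  for desk-scale totals (up to ~10^5), not deep production libraries.
* The mapper is exact end-to-end with substitutions only; indels,
  soft-clipping and quality-aware scoring are out of scope.
* ncRNA filtering is exact-substring, consistent with its
  filter-before-map role; diverged contamination passes it.
* Published sequencing-dependent magnitudes (DE counts, cluster counts,
  expressed-piRNA counts, target-mRNA counts) require the original raw
  libraries and external databases and are outside what a synthetic
  pipeline can or should reproduce; the package reproduces the
  procedures and the set arithmetic built on them.
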