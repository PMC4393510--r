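---
title: "sweepsv: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sweepsv: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepsv)
```

This vignette records the statistical model, the algorithmic conventions,
and the default parameters of `sweepsv`, including the choices that are not
forced by the problem and would otherwise be invisible to a reader of the
call output.

## 1. Library profiles and the discordance cutoff

Every sequencing library has its own fragment-size distribution, so all
thresholds are per `(sample, library)` — the library is taken from the
`RG` tag of each alignment (records without one fall into library
`"default"`).

From concordant-orientation pairs, `estimate_library_profile()` computes
the fragment-span median and MAD with two deliberate conventions:

* **lower median** for even sample sizes (the `n/2`-th order statistic),
  so the statistic is always an observed span and integer arithmetic stays
  exact;
* **unscaled MAD** (no 1.4826 normal-consistency factor), because the MAD
  is used as a robust spread unit for a cutoff, not as a sigma estimate.

The concordance cutoff is `W = round(median + k_mad · MAD)` with half-up
rounding (`round_half_up()`; R's `round()` rounds half to even, which
would make the cutoff depend on parity). The defaults are `k_mad = 8` for
production profiling (`profile_libraries()`, `sv_discover()`) — wide
enough that fragment-size tail pairs in a few-fold-coverage genome do not
flood the discordant stream — and profiling requires at least
`min_observations = 1000` spans per library (default), erroring rather
than emitting an unstable profile.

Classification of a canonicalized pair (ends ordered by chromosome, then
coordinate; `canonicalize_pairs()`):

* **discordant** — interchromosomal, non-(+,−) orientation, or outer span
  `max(end1, end2) − start1 > W`;
* **excluded** — (+,−) pairs with span below `median − k_mad·MAD`
  (undersized fragments are insertion-like signals, out of scope here);
* **concordant** otherwise.

## 2. Routing keys and partitioning

Discordant pairs are partitioned by the routing key
`(chrom1, chrom2, strand1, strand2)`. Within an FR library the key fixes
the rearrangement class: oversized (+,−) pairs span deletions, everted
(−,+) pairs span tandem-duplication junctions, (+,+)/(−,−) pairs span the
two inversion junction orientations, and any interchromosomal key is a
translocation. Each partition can be processed independently, which is
what makes the cohort-scale pipeline embarrassingly parallel after
extraction.

Partitions are spilled to a versioned TSV dialect (one pair per line,
fixed column order) under `workdir/spill/`, with a `partitions.tsv`
manifest, so every later stage can be run and inspected in isolation.

## 3. External sorting

Each partition is sorted by the key
`(start1, end1, chrom2, start2, sample_id, read_id)` under a configurable
memory budget (`memory_records`, default 500,000 records per in-memory
run). Implementation conventions chosen for determinism:

* sort keys are rendered as zero-padded decimal strings joined by a
  separator below all printable characters, so *byte-wise* line comparison
  equals tuple comparison, independent of locale;
* all ordering uses R's radix sort (C locale, stable);
* runs and merges are **line-verbatim**: records are never re-parsed and
  re-serialized, so the merged output is byte-identical regardless of the
  memory budget or run structure (asserted in the tests by comparing raw
  bytes across budgets);
* the k-way merge cascades hierarchically with a fan-in of 32, keeping the
  number of simultaneously open files bounded for partitions with many
  spill runs.

## 4. Breakpoint rectangles and sweep clustering

A discordant pair constrains each junction to an interval determined by
its library's cutoff `W`: for a `+` end mapped to `[s, e)` the junction
lies in `[e, s + W)`; for a `−` end in `[e − W, s)`. The two intervals
form the pair's *breakpoint rectangle*, and two pairs are **compatible**
when their rectangles overlap on both sides — a necessary condition for
them to straddle the same junction.

`sweep_cluster()` consumes one sorted partition and greedily grows
clusters:

* Members are processed in increasing order of the rectangle start `lo1`.
  The sorted stream is ordered by `start1`, which coincides with `lo1`
  order for a single library but **not** with mixed libraries (a pair with
  a larger `start1` but a smaller `W` can have a smaller `lo1`). Sweeping
  the raw stream would then close clusters that a later pair could still
  join. `sweep_cluster()` therefore checks the input is `start1`-sorted
  (errors otherwise) and stably re-sorts by `lo1` internally; the closure
  rule is sound by construction.
* A new pair joins the open cluster whose running intersection it overlaps
  the most (maximizing the smaller of the two per-side overlaps), ties
  going to the oldest cluster; otherwise it seeds a new cluster.
* An open cluster closes when the sweep position passes its side-1
  footprint (`footprint_hi1 ≤ lo1` of the current pair) — after that
  point no future pair can be compatible with all members.
* Clusters exceeding `cluster_cap` members are *dropped* and logged
  (`dropped_depth`), never reported: pathological pile-ups (collapsed
  repeats, reference artifacts) would otherwise dominate runtime and the
  call set. The default cap is `max(100, 10 · Σ sample depths)`
  (`default_cluster_cap()`), i.e. ten times the expected cohort-wide
  depth.

On fixtures whose true clusters are separated by more than `2W`, the
greedy result provably equals maximal-clique enumeration of the
compatibility graph; the test suite checks this against
`igraph::max_cliques` over hundreds of randomized fixtures.

A finalized call reports the **intersection** of member rectangles on both
sides (the tightest interval containing the junction under the model), the
member footprints, and per-sample support (`"S1:11;S2:9"`), ordered by the
sample sheet. Output is 13-column BEDPE, 0-based half-open.

## 5. Cohort analytics

`presence_matrix()` marks a call present in a sample when that sample
contributes at least `min_pairs` (default 1) supporting pairs.
`classify_breakpoints()` assigns **non-exclusive** labels against a
tumor–normal pairing: *germline* (present in ≥1 normal), *private*
(present in exactly one sample), *tumor_private* / *normal_private*. A
normal-private breakpoint is both private and germline; with this reading
the germline and tumor-private sets exactly tile the call set.

* `somatic_fdr()` = `100 · #normal_private / #tumor_private`: under the
  null that private calls arise in tumors and normals at the same rate,
  the normal-private rate estimates the false-discovery rate of
  tumor-private ("somatic") calls.
* `fdr_vs_n()` re-estimates that FDR when each focal pair is additionally
  screened against N random extra pairs (a call is discarded if seen in
  any screening genome), Monte-Carlo averaged over replicates. The curve
  is non-increasing in expectation: screening removes germline variants
  that the matched normal missed.
* `sample_clustering()` computes binary Jaccard distances
  (`vegan::vegdist`) on the presence matrix and average-linkage
  hierarchical clustering, exported as Newick via `ape`. Shared germline
  variation pairs each tumor with its matched normal.

## 6. Truth evaluation

`roc_curve()` compares deletion calls to a truth BED using fixed-width
probes (default 200 bp) centered on each breakpoint-interval midpoint
(clipped at zero). A call matches a truth variant when its probes
intersect the truth's probes at *both* ends; true positives count distinct
truth variants (a truth deletion found by several calls counts once), and
the support threshold is swept (default 4–10), which is monotone by
construction. `apply_exclusions()` removes calls and truth entries whose
probes touch excluded regions before evaluation.

## 7. The synthetic cohort simulator

`simulate_cohort()` generates alignment-level data with **no sequences**:
SAM records with fixed-length matches (`100M`), MAPQ 60 and TLEN 0, since
every downstream stage consumes coordinates, strands and read groups only.
Fixed study conditions:

* fragment lengths per library: Normal(median, 1.4826·mad) truncated at
  `2 · read_length` (the consistency factor makes the *configured* MAD the
  distribution's MAD, so profile recovery is testable);
* germline genotypes: Hardy–Weinberg at the configured allele frequency,
  redrawn until each variant has ≥1 carrier; a somatic fraction is
  assigned as heterozygous to a single random tumor;
* junction-spanning support: Poisson with mean
  `haplotypes · (depth/2) / (2·read_length) · (median − 2·read_length)`
  per junction — the expected number of fragments whose inner gap covers a
  point; inversions emit both junction orientations;
* planted translocations are interchromosomal only (an intrachromosomal
  exchange is signature-ambiguous with deletions/duplications, which would
  make truth labels ill-defined);
* optional uniform random noise pairs (`noise_rate`).

Deliberately **not** modeled: read-depth changes inside deleted or
duplicated intervals, split reads, base-level errors, mapping ambiguity
beyond a constant MAPQ. These do not affect a pure read-pair-geometry
caller, and their omission keeps every fixture generated in code.

`simulate_cohort_calls()` skips alignments entirely and generates finished
call tables for exercising the cohort analytics at scale: per-carrier
detection support is Poisson with `mean_support = 3` by default — the
discordant-pair yield of a heterozygous variant in a few-fold-coverage
genome, the regime in which population screening matters, under which
carriers are regularly missed (support 0) and joint calling has something
to rescue.

## 8. Problem sizes exercised

The test suite runs each stage well beyond toy size: a 10,000-record
external sort at three memory budgets (including one record per run), a
three-library 30× genome with 50 planted deletions recovered end-to-end
(recall ≥ 0.95 at zero false positives), 200 randomized clustering
fixtures checked against exhaustive enumeration, and cohort matrices up to
33,218 breakpoints × 129 samples for the estimator chain.
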