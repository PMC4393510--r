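# sweepsv

Population-scale structural-variant (SV) discovery from discordant
paired-end alignments, in R.

Paired-end sequencing libraries have a characteristic fragment-size
distribution. A read pair whose two ends map too far apart, in the wrong
orientation, or on different chromosomes is *discordant*: it straddles a
rearrangement junction. `sweepsv` profiles each library's fragment sizes,
extracts discordant pairs across a whole cohort at once, and clusters
compatible pairs into breakpoint calls with per-sample support — so a
variant seen weakly in many shallow genomes is still called, and a matched
tumor–normal design yields an internal estimate of the somatic false
discovery rate.

## The model in one paragraph

For each library, the fragment-size median and MAD (lower median, unscaled
MAD) define a concordance cutoff `W = round(median + k·MAD)` (default
`k = 8`). A pair is discordant if it is interchromosomal, not in (+,−)
orientation, or spans more than its library's `W`. Each discordant end
implies a *breakpoint rectangle* — the interval where the junction must lie
given `W` — and two pairs are compatible when their rectangles overlap on
both sides. Pairs are partitioned by routing key
`(chrom1, chrom2, strand1, strand2)` (which fixes the SV class: deletion,
tandem duplication, inversion, or translocation), externally sorted with a
bounded memory budget, and greedily clustered by a sweep line that closes a
cluster once the sweep has passed its footprint. Calls carry the
intersection of member rectangles as breakpoint intervals and a per-sample
support string like `S1:11;S2:9`.

## Worked example

Simulate a two-sample cohort with two libraries per sample and five planted
SVs, then run the full pipeline:

```r
library(sweepsv)

cfg <- sim_config(
  chrom_lengths = c(chr1 = 800000L, chr2 = 400000L),
  samples  = data.frame(sample_id = c("S1", "S2"), role = c("tumor", "normal"),
                        pair_id = "P1", depth = c(10, 10)),
  libraries = data.frame(library_id = c("libA", "libB"),
                         median = c(300, 450), mad = c(15, 30)),
  sv_counts = data.frame(class = c("deletion", "tandem_duplication", "inversion"),
                         n = c(3, 1, 1), min_size = 3000, max_size = 15000),
  allele_freq = 1, seed = 42)
sim <- simulate_cohort(cfg, file.path(tempdir(), "demo"))

res <- sv_discover(sim$sample_sheet, workdir = file.path(tempdir(), "wd"),
                   min_observations = 100, min_support = 4)
res$profiles
```

```
   sample_id library_id median   mad k_mad max_concordant_span     n
1:        S1       libA    300    15     8                 420 29958
2:        S1       libB    450    30     8                 690 30102
3:        S2       libA    300    15     8                 420 29989
4:        S2       libB    450    30     8                 690 29904
```

The configured library parameters (300±15, 450±30) are recovered from the
alignments, and each library gets its own cutoff. The calls:

```r
res$calls[, .(call_id, svclass, chrom1, start1, end1, start2, end2,
              total_support, support)]
```

```
      call_id            svclass chrom1 start1   end1 start2   end2 total_support     support
1: INV_000001          inversion   chr1 323498 323739 331905 332098            19  S1:9;S2:10
2: DEL_000002           deletion   chr1  76350  76565  88417  88654            20  S1:11;S2:9
3: INV_000003          inversion   chr1 323289 323514 331661 331906            23 S1:10;S2:13
4: DEL_000004           deletion   chr2  56420  56621  69982  70232            17   S1:8;S2:9
5: DEL_000005           deletion   chr2 229721 229961 242797 243026            17  S1:7;S2:10
6: DUP_000006 tandem_duplication   chr2 197633 197893 204827 205060            22  S1:8;S2:14
```

All five planted variants are recovered with their true junctions inside
the reported intervals (the inversion yields one call per junction
orientation, as expected for read-pair signatures), with support from both
samples. `write_bedpe(res$calls, "calls.bedpe")` writes the standard
13-column BEDPE.

### Cohort analytics

For a tumor–normal cohort, presence/absence of each breakpoint across
samples drives the downstream estimators:

```r
presence <- presence_matrix(calls, sheet$sample_id)
pairing  <- sample_pairing(sheet)
labels   <- classify_breakpoints(presence, pairing)
somatic_fdr(labels)                 # 100 · normal-private / tumor-private
fdr_vs_n(presence, pairing, n_values = c(0, 5, 10), seed = 1)
sample_clustering(presence)         # Jaccard + average linkage, Newick tree
```

`roc_curve(calls, truth_bed)` evaluates deletion calls against a truth set
using 200-bp probes at both breakpoints, with optional exclusion regions
(`apply_exclusions`) and a support-threshold sweep.

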