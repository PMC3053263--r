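# chipcompare

Tools for comparing protein–DNA interaction profiles measured by tiling
microarray (ChIP-chip) and by high-throughput sequencing (ChIP-seq), with
an emphasis on what the *input DNA* (background) library does to every
downstream result.

## The problem

ChIP-chip and ChIP-seq measure the same biology through different
instruments, and each instrument leaves fingerprints in the data:
sequencing input libraries show a local-GC dependence of read density and
their stability depends on sequencing depth; arrays only measure where
probes exist (~70% genomic coverage is typical), compress dynamic range,
and carry probe-level dye effects. Anyone comparing platforms — or simply
choosing which input library to normalize against — needs statistics that
make these effects visible and a controlled setting in which they are the
*only* thing that varies.

`chipcompare` provides:

* **Profile construction** — 50 bp binning, read shifting, a normalized
  Gaussian smoother (bandwidth 50 bp, 400-neighbor truncation), log2
  IP/input enrichment with library-size scaling, log2 input profiles, and
  20-fold aggregation to 1 kb, with probe and input-variability masks.
* **QC statistics** — truncated skewness (signal-to-noise proxy: the third
  standardized moment after trimming 5% from each tail), masked Pearson /
  Spearman profile correlations, Spearman correlation with GC content,
  average-linkage correlation heatmaps, genomic coverage, and
  depth-subsampling coverage curves (ladder 90%…10%, 5%, 1%).
* **A platform-agnostic heuristic peak caller** — per chromosome, bins
  above `x̄ + k·s` are merged into regions; a region of `m` bins with
  enrichment sum `l` gets the upper-tail p-value of `N(m·x̄, m·s²)`;
  Benjamini–Hochberg FDR at 0.05. Peak-set concordance as the average (or
  smaller-set) proportion of overlapping peaks, and top-N ranking.
* **Meta-profiles** — strand-aware averages of the 80 × 50 bp bins in
  ±2 kb windows around TSS/TES of genes ≥ 2 kb, z-scaled to mean 0 and
  variance 1.
* **A synthetic-data generator** — toy genomes with smooth GC tracks,
  planted narrow/broad enrichment regions with known effects, GC-biased
  Poisson read sampling, two-channel probe intensities with configurable
  coverage, noise, and design-level dye bias, and binomial read thinning —
  so every statistic above can be validated against planted truth.

## Worked example

```r
library(chipcompare)

genome <- make_genome(n_chrom = 1, lengths = 1e6, seed = 11)
planted <- plant_regions(genome, 40, seed = 12)          # known truth
chip    <- simulate_reads(planted$lambda, genome, 1e6, seed = 13)
input   <- simulate_reads(constant_track(genome), genome, 1e6, seed = 14)

prof <- seq_enrichment(chip, input, genome)              # smoothed 50 bp
peaks <- call_peaks(aggregate_bins(prof, 20))            # 1 kb, k = 0
peaks
#> PeakSet: 55 regions (32 significant at FDR < 0.05), k = 0
peak_stats(peaks)
#> $count        [1] 32
#> $median_width [1] 5000
#> $mean_width   [1] 4656.25
truncated_skewness(prof)
#> [1] 1.915573
```

Thirty-two significant regions recover the planted enrichment (40 regions
were planted; closely spaced ones merge at 1 kb resolution), and the
positive truncated skewness (~1.9) says the enrichment distribution has
the long right tail of a profile with good signal-to-noise.

The whole study design runs as one orchestrated experiment:

```r
run_experiment(default_config(seed = 1), "demo_out")
```

which writes (among ~25 plain-text files) `skewness.tsv`,
`gc_correlation.tsv`, `peak_stats.tsv` and TSS/TES meta-profile tables.
From the default configuration, the GC-correlation table shows the design
working as intended — the deliberately GC-biased input library is flagged
while the unbiased one is clean:

```
input    spearman_gc
plain    -0.0235
biased    0.9010
```

and identical configuration + seed reproduce every output byte-for-byte
(`manifest.json` records parameters, seeds and versions).

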