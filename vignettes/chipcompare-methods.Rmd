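---
title: "Methods: comparing ChIP-chip and ChIP-seq signal profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing ChIP-chip and ChIP-seq signal profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcompare)
```

## What this package is for

Chromatin immunoprecipitation read out on a tiling microarray (ChIP-chip)
or by high-throughput sequencing (ChIP-seq) measures the same underlying
biology through two very different instruments. Each platform adds its own
background structure: sequencing libraries of input DNA carry a local-GC
dependence of read density, arrays measure only where probes exist and
compress the dynamic range, and both add noise of different character. The
package implements a compact analysis framework for studying such
platform effects — profile construction, signal-to-noise and
reproducibility statistics, a deliberately simple platform-agnostic peak
caller, average profiles around transcription start/end sites (TSS/TES),
and input-library quality control — together with a synthetic-data
generator that emulates *both* platforms from one shared enrichment
signal, so that every stage can be checked against planted ground truth.

## Profile construction

The working representation is a per-chromosome vector of fixed-width bins
(default 50 bp, 0-based half-open; bin *i* covers `[(i-1)b, ib)` and its
center sits at `(i-1/2)b`). For sequencing data, each read's stored 5'
position is optionally shifted by half the fragment length toward the
fragment midpoint (`shift_reads()`; the sign and magnitude are plain
arguments because strand conventions differ between pipelines), and
shifted positions are counted into bins. For array data, each probe's two
channel intensities are assigned to the bin containing the probe midpoint
and averaged within bins; bins without probes are masked out.

Both kinds of track are smoothed with a normalized Gaussian kernel,

$$\hat y_i = \frac{\sum_j w_{ij}\, y_j}{\sum_j w_{ij}},
  \qquad w_{ij} = \exp\!\left(-\frac{(x_j - x_i)^2}{2\,h^2}\right),$$

with bandwidth `h = 50` bp and the sum truncated to the 400 nearest bins
(200 per side), which at this bandwidth is numerically indistinguishable
from the full kernel. The normalization makes the smoother preserve
constants and behave linearly, two properties the tests rely on. An
unnormalized variant (the raw weighted sum) is available behind
`normalize = FALSE` for comparison.

Enrichment is the log2 ratio of (smoothed) IP over input. For count
tracks a pseudocount of 0.5 is added to both channels and each channel is
divided by its genome-wide total first; this library-size scaling centers
genome-wide mean enrichment near zero, which is also the centering
assumption of the peak caller's threshold at `k = 0`. Intensity tracks
use no pseudocount (intensities are strictly positive) and no scaling.
Smoothing is applied to the channels *before* the ratio; the ratio of
smoothed channels is better behaved at low counts than a smoothed ratio.
Input libraries, which have no IP channel, are summarized as
`log2(value + pseudocount)` (`input_profile()`).

For genome-wide comparisons, every 20 adjacent 50 bp bins are averaged to
1 kb resolution (`aggregate_bins()`); only masked-in child bins enter the
average, and an output bin is masked out only when all its children are.
Cross-platform comparisons additionally mask bins without probes and bins
whose input-library variability exceeds the 0.95 genome-wide SD quantile
(`variability_mask()`), so correlations are not driven by coverage gaps
or unstable background.

## Signal-to-noise and reproducibility

The signal distribution of a profile is summarized by its skewness after
discarding the lowest and highest 5% of values by rank,

$$\mathrm{skew}(x) = \frac{\tfrac1n\sum_i (x_i-\bar x)^3}
  {\left[\tfrac1n\sum_i (x_i-\bar x)^2\right]^{3/2}},$$

computed with 1/n moments. Trimming makes the statistic a property of the
bulk of the distribution; a strongly positive value means a long right
tail, i.e. distinct enrichment above background. Reproducibility between
profiles is the Pearson correlation on jointly masked-in bins (Pearson is
more sensitive than Spearman to the enriched tail, which is what matters
for ChIP signal); GC-bias diagnostics use Spearman, since any monotone
response of read density to GC should count fully.

With two replicates that share a signal of variance $\sigma_s^2$ and
carry independent noise of variance $\sigma_n^2$, the expected replicate
correlation is the attenuation ratio
$\sigma_s^2 / (\sigma_s^2 + \sigma_n^2)$. Because the generator's signal
and noise variances are known, this closed form serves as an independent
check of the whole array pipeline (see the acceptance script).

## The heuristic peak caller

The caller is intentionally simple so that it can be applied identically
to both platforms. Per chromosome, let $\bar x$ and $s$ be the mean and
SD of the masked-in enrichment values. Step 1 selects bins with values
above $\bar x + k s$ (default `k = 0`) and merges maximal runs of
adjacent selected bins into candidate regions; a masked-out bin breaks a
run. Step 2 assigns each region of $m$ bins with value sum $l$ the
upper-tail probability of $L \sim N(m\bar x,\, m s^2)$:

$$p = 1 - \Phi\!\left(\frac{l - m\bar x}{s\sqrt m}\right).$$

q-values are Benjamini–Hochberg adjusted across all regions genome-wide
and regions with `q < 0.05` are called significant. Two caveats are
faithfully reproduced rather than corrected: the null assumes independent
bins (smoothing-induced autocorrelation makes it anti-conservative at
fine resolution), and only above-threshold runs are tested (a selection
bias). The caller is a comparison instrument, not a state-of-the-art
detector.

Numerical conventions: region coordinates keep `end - start = m * bin`,
even for a trailing partial bin; `top_peaks()` breaks p-value ties by
larger `l` and then genomic order so rankings are reproducible; a
constant (zero-variance) chromosome is an error rather than a silent
empty result.

Peak-set concordance uses the proportion of regions in one set that
intersect the other by at least 1 bp, either averaged over both
directions or reported for the smaller set.

## Meta-profiles at TSS and TES

Genes shorter than 2 kb are excluded (inclusive bound at exactly 2 kb) so
that ±2 kb windows do not cross both gene ends. For each anchor the 80
flanking bins of 50 bp are extracted, reversed for minus-strand genes so
position 1 is always 2 kb upstream in the gene's own orientation
(orientation-aware averaging is required for TSS/TES asymmetry to be
visible at all), and averaged per position over sites with a usable value
there — masked bins are skipped position-wise rather than dropping whole
sites, which preserves sample size at array coverage gaps. Profiles are
z-scaled to mean 0, variance 1. Overlapping genes are not deduplicated;
each gene record contributes one window.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once:

* **Genome**: two chromosomes of 500 kb (1 Mb for the larger recovery and
  reproducibility runs), GC track at 50 bp with mean 0.42
  (fruit-fly-like), maximum deviation 0.10, and a 10 kb correlation
  length, built from Gaussian-smoothed white noise rescaled per
  chromosome and clipped to [0.05, 0.95].
* **Truth**: non-overlapping regions in two width classes — narrow
  U(500, 1500) bp and broad U(2000, 8000) bp, an even mix — with uniform
  effect multipliers (4–8 for recovery runs; 1.5–4 where weak peaks near
  the detection limit are the point). The rate track λ is 1 outside
  regions and the effect inside.
* **Reads**: per-bin sampling rate λ·exp(β·(gc − mean gc)); the
  exponential tilt guarantees positive rates and a Spearman-monotone,
  tunable GC bias. Totals are Poisson around the requested depth;
  fragment midpoints are drawn per bin, strands are uniform, the 5'
  position is offset by ±frag_len/2 (fixed fragment length 200 bp, reads
  36 bp — length variability is never used by the analyses).
* **Arrays**: probes tile at 50 bp; random contiguous blocks (mean 5 kb)
  are dropped until genomic coverage hits the 70% target, so missing
  coverage looks like real probe-design gaps rather than salt-and-pepper.
  Channels get independent log-normal noise (`noise_sd`, default 0.3 in
  log2). Two optional design-level effects are shared by replicate
  hybridizations of the same `design_seed`: a response exponent `gamma`
  (dynamic-range compression) and a probe-specific dye bias
  (`dye_bias_sd`), the well-documented probe-sequence-dependent dye
  effect of two-colour arrays. The dye bias is what gives replicate
  arrays a platform-specific shared component — without any such
  component, the cross-platform correlation of matched profiles is the
  geometric mean of the two intra-platform correlations and can never lie
  below both, whereas real cross-platform comparisons do lie below both.
* **Subsampling**: independent per-read thinning; the default ladder is
  90%, 80%, …, 10%, 5%, 1%.
* **Seeds**: one master seed fans out to per-stage child seeds
  (`child_seed()`), so stages re-run independently and the whole pipeline
  is bit-for-bit reproducible.

What the generator deliberately does **not** model: sequence-level reads
(no FASTQ, mappability, or duplicates), chromatin-structure, CNV or
repeat covariates of input density, fragment-length variability, dye-swap
designs, or array spatial artifacts. Tests passing on this generator
therefore demonstrate the correctness and internal consistency of the
statistics, not their robustness to every bias of real data.

## Analysis configurations used by the tests and the acceptance script

* **Recovery** (50 regions, effects 4–8, 2×10⁶ reads on 1 Mb, 20 seeds)
  calls peaks on the smoothed 50 bp profile: base-level precision is a
  localization measure and is assessed at the profile's native
  resolution. Mean recall and base-level precision both exceed 90% at
  FDR 0.05.
* **Input-swap peak calling** (80 regions, effects 1.5–4, deep vs 1%
  input, 20 seeds) calls peaks on the 1 kb aggregated profile — the
  resolution at which profiles are characterized genome-wide. The weak
  end of the effect range is essential: with only strong peaks both
  backgrounds saturate and the detection-power difference disappears, and
  at 50 bp the shallow input's smoothing-correlated noise instead
  inflates the count through the caller's independence assumption.
* **Input-swap meta-profiles** use a broadly depleted mark (effect 0.3
  across gene bodies and flanks, as for a repressive modification), GC
  bumps planted at TSSs, and a ChIP normalized against either a strongly
  GC-biased (β = 5) or an unbiased input: only the mismatched
  normalization leaves a GC-shaped residual in the TSS profile.
* **Reproducibility** compares unsmoothed 50 bp profiles, where the
  attenuation algebra is exact: array replicates share a design
  (`dye_bias_sd = 0.5` for the ordering run, 0 for the attenuation
  check), sequencing replicates share a GC bias (β = 6) that their
  unbiased inputs fail to cancel, and the cross-platform pair shares only
  the planted signal.

Problem sizes (1 Mb genomes, ≤2×10⁶ reads, 20-seed averages) were chosen
so the full suite completes in a few minutes on one CPU while keeping
binomial/Poisson fluctuations well inside the asserted tolerances.

## A worked demonstration

```{r demo, eval = FALSE}
out <- run_experiment(default_config(seed = 1), "demo_out")
list.files(out)
```

`run_experiment()` writes every intermediate as plain text (BED,
bedGraph, TSV) plus a `manifest.json` recording parameters, seeds and
versions; the same configuration and seed reproduce every file
byte-for-byte.

## Known limitations

* The peak caller's normal null is anti-conservative under smoothing;
  this is a property of the method being studied, kept on purpose.
* GC bias is the only input-DNA covariate modeled; conclusions about
  other background structure (chromatin state, CNV, repeats) are out of
  reach of the generator.
* The log2 choice for enrichment affects scale only, not ranks, peaks or
  correlations; natural log would give identical results up to the
  constant factor.
* Array probes are tiled at a single spacing; real designs with variable
  probe density would make the probe mask, not the spacing, the binding
  constraint — the mask machinery is shared either way.
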