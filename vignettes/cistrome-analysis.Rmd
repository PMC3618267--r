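---
title: "Characterizing transcription-factor cistromes: methods and design notes"
author: "CistromeKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing transcription-factor cistromes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CistromeKit)
```

This vignette is the package's own account of the statistics it
implements, the parameters that matter, the numerical conventions
chosen where the underlying methods leave room, and what the synthetic
validation does and does not establish.

# The similarity score and its conventions

A motif is a position-specific frequency matrix (PSFM): per-position
frequencies $P_{ij}$ over $\{A, C, G, T\}$ with background frequencies
$Q_i$. Column $j$ is weighted by its information content

$$I_j = \sum_{i} P_{ij} \log_2 \frac{P_{ij}}{Q_i},$$

with $P \log P = 0$ at $P = 0$, and a sequence selecting letter $i(j)$
at each position scores

$$S = \frac{\sum_j I_j\,(2P_{i(j),j} - 1)}{\sum_j I_j\,(2P^{\max}_j - 1)}.$$

Conventions adopted here:

* **Log base.** $I_j$ is reported in bits (base 2). $S$ itself is
  base-invariant — the base change multiplies every $I_j$ by the same
  constant, which cancels between numerator and denominator — and the
  test suite checks this numerically against natural-log weights.
* **Threshold sense.** A window is *matched* when $S \ge t$. The
  alternative strict inequality would make $t = 1$ unreachable even by
  the consensus; with $\ge$, $t = 1$ selects exactly the sequences that
  pick a maximum-frequency letter at every informative column.
* **Zero frequencies.** Matrices read as counts are not pseudocounted
  by default (`pseudocount = 0` in `PSFM()`); zeros are legal in $S$
  through the $0 \log 0 = 0$ convention. A pseudocount is available for
  users who want sampled planting or softer matrices.
* **Degenerate matrices.** If every column is uniform the denominator
  is zero and scoring errors out ("uninformative PSFM") rather than
  returning 0/0.
* **Strands.** Scanning covers both strands by default; a window
  passing on both is counted once with the better strand reported. The
  minus strand is scored by reverse-complementing the matrix, which is
  exactly equivalent to scanning the reverse-complemented sequence.

## Masking and effective length

Genomes are held as case-preserving `BStringSet`s: lowercase bases are
soft-masked repeats and `N` is hard-masked. A window is scorable only
if all of its bases are uppercase A/C/G/T. The effective length
$L$ of a region set — the denominator of match density — is its count
of unmasked *bases*, not of scorable windows. The two differ by edge
effects of order the motif length per masked run; at realistic masked
fractions this is a sub-percent distinction and the base count is the
convention that matches a "repeat-masked sequence length".

# Enrichment statistics

Matched counts are modelled as binomial over the effective length; for
small per-base probability the count is approximately normal with mean
and variance both equal to $E = N_c L_s / L_c$, giving the fold
enrichment $F = N_s / E$ and $Z = (N_s - E)/\sqrt{E}$. Choices:

* The **background set is an explicit argument** everywhere. Enrichment
  against an unstated genome-wide background makes results
  irreproducible across masking and assembly choices; requiring the set
  keeps the contract explicit. The synthetic generator provides
  matched background region sets.
* When $N_c = 0$, $F$ and $Z$ are `NA` (undefined), never infinities.
* When $E < 10$ the result carries a `lowExpected` flag: the normal
  approximation assumes $np$ large, and at small $E$ the Z-score's null
  distribution is visibly discrete and skewed.
* Overlapping matched windows within a region are counted
  individually; $N$ is a window count. Collapsing overlapping matches
  to one would make $N$ depend on the threshold in a discontinuous way.

The test suite calibrates the statistic directly: 1,000 seeded binomial
replicates at $E = 100$ must give $Z$ with mean in $[-0.1, 0.1]$,
variance in $[0.85, 1.15]$ and an $|Z| > 1.96$ exceedance rate between
3.5% and 6.5% (the exact binomial tail at this $E$ is just over 5%).

# Peak annotation

Each peak is reduced to a point anchor — its summit, falling back to
the region midpoint — and classified against gene models with
gene-oriented distances (negative = upstream of the TSS):

| class | interval (bp, gene-oriented) |
|---|---|
| proximal promoter | $[\mathrm{TSS}-2000,\ \mathrm{TSS}+1000]$, closed |
| gene body | $(\mathrm{TSS}+1000,\ \mathrm{TES}]$ |
| upstream enhancer | $[\mathrm{TSS}-50000,\ \mathrm{TSS}-2000)$ |
| downstream enhancer | $(\mathrm{TES},\ \mathrm{TES}+50000]$ |
| distal intergenic | beyond 50 kb from every TSS and TES |

When several genes yield classes the highest-priority class wins
(promoter > gene body > upstream > downstream), ties break by smaller
$|$distance to TSS$|$, then lexicographic gene name, so the assignment
is a deterministic partition. Design notes:

* **Point anchor rather than any-overlap.** A 500 bp peak can straddle
  a promoter edge; overlap-based rules then need their own
  tie-breaking and can double-assign. The summit is the best single
  estimate of the binding position and guarantees uniqueness. The
  boundary placements (which side of each edge is closed) are not
  dictated by the kb figures themselves; they are fixed as above and
  unit-tested at every edge.
* Each transcript record is one gene model; no isoform collapsing is
  attempted beyond counting distinct gene names where gene-level counts
  are reported.

# Summit-aligned profiles

Profiles expand every anchor by a half-width $W$ (default 3,000 bp,
giving $2W + 1$ positions including the summit at 0) and average
per position across anchors, reading minus-oriented anchors
right-to-left so all profiles run 5′→3′ in the orientation of the
annotated gene; distal intergenic anchors are taken as plus-strand.
Missing track values (conservation tracks have gaps) are excluded from
the per-position mean rather than imputed as zero — imputing zero
biases profiles downward wherever coverage is sparse; the
`missingAsZero` flag provides the alternative. Anchors near chromosome
edges contribute only their in-bounds positions.

Tag-density profiles count single-bp tag positions in windows of
500 bp (the standard visualization window for this kind of data)
stepping by 10 bp by default, normalized to tags per bp per anchor.
The window size trades resolution against shot noise; the step only
controls output granularity.

# Overlap and comparative analyses

* **Overlap criterion**: at least 1 shared bp, configurable via
  `minOverlap`. One base pair is the weakest defensible criterion and
  the one that makes counts insensitive to peak-width conventions.
* **Directional counting**: `overlapPartition()` counts *regions of
  each set* that touch the other set, not merged intersections, so
  `nAandB` and `nBandA` can differ; covered percentages are consistent
  with the partition by construction
  (`fraction * n == nAandB`), which the tests assert.
* The paired comparison of covered fractions is the standard paired
  $t$: $t = \bar d / (s_d/\sqrt n)$ with $n - 1$ df, cross-checked in
  the tests against `stats::t.test`. Zero-variance nonzero differences
  report the smallest positive double rather than 0.
* Chromosome-level correlations are squared Pearson correlations of
  per-chromosome peak counts against distinct gene-name counts and
  chromosome lengths (from a `chrom.sizes` input; ungapped lengths are
  not distinguished).

# The synthetic-data generator

The generator is a first-class module: every input the pipeline
consumes can be produced with recorded ground truth, and each generator
is a pure function of its seed.

What it emulates, and the defaults chosen as realistic for this kind of
study:

* **Genome**: i.i.d. bases at 41% GC (the human genome-wide figure),
  10% soft-masked in 300 bp runs by default. Real repeat structure,
  CpG islands and compositional heterogeneity are *not* emulated.
* **Gene models**: one gene per 150 kb slot with ≥ 50 kb flanks, so
  category windows of neighboring genes never interleave and a planted
  category is unambiguous under the priority rule. Real gene ends
  overlap and nest; the annotation code handles that (priority +
  tie-breaks), but the generator deliberately avoids it so truth is
  exact.
* **Peaks**: categories and motif classes are apportioned by largest
  remainder, so the designed mixes are hit exactly; summits are placed
  inside the demanded window; peaks are mutually disjoint. Peak width
  defaults to 301 bp (±150), in the range of sharp ChIP-seq peaks, and
  fold enrichments are lognormal with median ≈ 25, matching the scale
  of a deeply sequenced factor.
* **Motif planting**: the default plants exact consensus instances
  (ties among maximum-frequency letters resolved at random), which
  makes composition recovery threshold-insensitive; `plantMode =
  "sample"` draws instances from the matrix for enrichment-recovery
  experiments. After planting, each peak's sequence is *scrubbed*:
  re-classified at the stated thresholds and resampled until the
  realized class equals the planted one, so chance matches cannot blur
  the designed composition. Density-planting
  (`generatePlantedDensitySet()`) does not scrub; its recovery tests
  instead measure the chance-hit rate on an unplanted run and fold it
  into the expectation.
* **Conservation tracks**: triangular bumps (height 0.9, width 1 kb
  over baseline 0.1) at summits, merged by maximum. Real phastCons is
  bounded, gapped and noisy; the bump shape only needs to make
  summit-centering and orientation handling falsifiable.
* **Co-bound sets**: exactly $\lfloor f \cdot n \rfloor$ regions
  overlap distinct base peaks; the rest are placed disjoint, so overlap
  partitioning has integer ground truth.
* **Tags**: normal draws around summits (sd 100 bp, clamped at
  ±3 sd) over a uniform background.

Because the generator plants consensus instances into otherwise random
sequence, passing recovery tests shows the *computational* pipeline is
correct — coordinates, strand handling, thresholds, bookkeeping — not
that the default reconstruction matrices would quantify a real
cistrome's composition accurately; for real data, matrices from a
curated database should be supplied.

## Shipped matrices are reconstructions

The three bundled motifs — the extended PU.1 element
(A/G)AAAG(A/G)GGAAGTG, the canonical element AG(A/G)GGAAG and the
retinoic-acid response element half site AGGTCA — are built from their
consensus strings (fixed letters at 0.94, two-fold degenerate letters
split 0.48/0.48), because no numeric matrices are published alongside
the consensi. They are labelled reconstructions in their file names and
documentation and are intended for testing and demonstration;
`readPSFM()` accepts TRANSFAC and plain-matrix files for real analyses.

# Coordinates

Internally everything is a `GRanges` in the 1-based closed Bioconductor
convention; only readers and writers convert. BED input (0-based
half-open) and MACS-style peak tables (1-based inclusive, summit as
offset from start) round-trip bit-for-bit, which the suite checks on
randomized region sets. Keeping a single internal convention — and
putting every conversion behind `readRegions()`/`writeRegions()` — is
what eliminates off-by-one bug classes; which convention is chosen
matters less than that there is exactly one.

# Problem sizes

The validation suite runs at desk scale, chosen so the whole suite
completes in about two minutes: genomes of 3 × 1.2 Mb, 20-ish genes,
100-peak sets, 1,000-replicate null calibrations, and planted-density
scans over ~0.75 Mb of sequence. These sizes put the stochastic checks
(fold-enrichment recovery, Z calibration, flat-profile bounds) at
3-sigma tolerances of a few percent; all deterministic checks
(coordinates, boundaries, partitions, designed mixes and overlap
counts) are exact at any size.

# Known limitations

* The scanner is a faithful, window-by-window implementation in R; for
  genome-scale scans (hundreds of Mb) a compiled scanner would be
  preferable. At the region-set scale the package targets (10⁴–10⁵
  peaks × ~500 bp) it is adequate.
* Score tracks are held per-base as run-length vectors; bigWig input is
  not supported — convert to bedGraph/wiggle text first.
* The binomial enrichment model ignores compositional bias between
  sample and background; users should choose background sets matched
  in GC and masking (the generator does).
* Multi-isoform genes are treated as independent gene models.
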