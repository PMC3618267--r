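# CistromeKit

Tools for characterizing a transcription factor's cistrome — the
genome-wide set of its in vivo binding regions from a ChIP-seq
experiment — built around the kind of questions asked of the PU.1
cistrome in acute promyelocytic leukemia cells: which known sequence
elements are enriched in the bound regions, where the regions sit
relative to genes, how conserved they are around their summits, and how
they overlap the binding of other factors such as PML/RARα.

It is aimed at computational biologists who have peak calls (MACS-style
tables or BED), a genome FASTA, gene models and per-base score tracks,
and want the downstream characterization steps as tested, reusable R
functions rather than one-off scripts. A fully seeded synthetic-data
generator produces every input with recorded ground truth, so the whole
pipeline is testable end to end without downloads.

## The statistics at the core

**Motif similarity.** A motif is a position-specific frequency matrix
(PSFM) with per-position letter frequencies *P<sub>ij</sub>* and
background frequencies *Q<sub>i</sub>* (0.25 each by default). Each
column is weighted by its information content

> *I<sub>j</sub>* = Σ<sub>i∈{A,C,G,T}</sub> *P<sub>ij</sub>*
> log₂(*P<sub>ij</sub>*/*Q<sub>i</sub>*),  with 0·log 0 = 0,

and a sequence of the motif length scores

> *S* = Σ<sub>j</sub> *I<sub>j</sub>*(2*P<sub>i(j),j</sub>* − 1) /
> Σ<sub>j</sub> *I<sub>j</sub>*(2*P<sub>j</sub><sup>max</sup>* − 1),

where *i(j)* is the letter observed at position *j*. *S* = 1 exactly at
a consensus sequence and is invariant to the log base. Windows slide at
1 bp over each region; soft-masked (lowercase) and N bases make a
window unscorable, and the effective length *L* of a region set is its
count of unmasked bases.

**Enrichment.** With *N<sub>c</sub>* matched windows in a background
set of effective length *L<sub>c</sub>* and *N<sub>s</sub>* in a sample
set of length *L<sub>s</sub>*, the matched count is modelled as
binomial, approximated by a normal with equal mean and variance:

> *E* = *N<sub>c</sub>* · *L<sub>s</sub>* / *L<sub>c</sub>*,
> *F* = *N<sub>s</sub>* / *E*,
> *Z* = (*N<sub>s</sub>* − *E*) / √*E*.

**Annotation.** Each peak is anchored at its summit and assigned one
class relative to gene models — proximal promoter (−2 kb to +1 kb of
the TSS), gene body (TSS+1 kb to TES), upstream enhancer (−50 kb to
−2 kb), downstream enhancer (TES to +50 kb) or distal intergenic
(> 50 kb from every TSS/TES) — with the priority rule
promoter > gene body > upstream > downstream > distal, so the classes
partition the peak set.

Around these sit summit-aligned, gene-oriented mean profiles of
conservation-style tracks and tag densities; long/short/neither motif
composition of peak sets (a peak matching both elements counts as
long); overlap partitions, covered percentages and paired t
comparisons; and chromosome-level peak-count correlations.

## Worked example

Simulate a study-scale setup — 100 peaks planted with the genomic
distribution and motif composition used throughout the package's tests
— and recover the ground truth:

```r
library(CistromeKit)
motifs <- defaultMotifs()   # consensus-derived PU.1 long/short + RAREh

sim   <- generateGenome(nChroms = 3, chromLength = 1.2e6, seed = 7)
genes <- generateGeneModels(sim, 20, seed = 7)$genes
peaks <- generatePeaksWithMotifs(sim, genes, 100,
           categoryMix = c(promoter = 0.14, gene_body = 0.42,
                           upstream_enhancer = 0.165,
                           downstream_enhancer = 0.099,
                           distal_intergenic = 0.176),
           classMix = c(long = 0.371, short_only = 0.463, neither = 0.166),
           seed = 7)

annotatePeaks(peaks$peaks, genes)$distribution
#>              category count percent
#> 1            promoter    14      14
#> 2           gene_body    42      42
#> 3   upstream_enhancer    16      16
#> 4 downstream_enhancer    10      10
#> 5   distal_intergenic    18      18

motifComposition(peaks$peaks, peaks$genome$genome,
                 motifs$long, motifs$short)
#> Motif composition of 100 peaks
#>   long:       37 (37.0%)
#>   short only: 46 (46.0%)
#>   neither:    17 (17.0%)
```

The planted category mix (14/42/16/10/18) and motif classes (37/46/17)
are recovered exactly: placement and planting are deterministic given
the seed, and the generator scrubs chance motif matches.

Enrichment of a motif planted at 5× background density:

```r
fg <- generatePlantedDensitySet(300, 500, 1e-3, motifs$long,
                                seed = 8, chromName = "fg")
bg <- generatePlantedDensitySet(600, 1000, 2e-4, motifs$long,
                                seed = 9, chromName = "bg")
g <- c(fg$genome, bg$genome)
s_fg <- scanRegions(motifs$long, fg$regions, g, threshold = 0.8)
s_bg <- scanRegions(motifs$long, bg$regions, g, threshold = 0.8)
enrichmentStats(s_fg$n, s_fg$lEff, s_bg$n, s_bg$lEff, motif = "PU1_long")
#> EnrichmentResult 'PU1_long'
#>   sample:     N_s = 148 in L_s = 150000 bp
#>   background: N_c = 108 in L_c = 600000 bp
#>   E = 27, fold enrichment F = 5.481, Z = 23.29
```

The fold enrichment lands near the designed 5× (chance matches add a
little to both sets), with a strongly positive Z.

## Documentation

The methods vignette (`vignettes/cistrome-analysis.Rmd`) describes the
models, parameter choices, numerical conventions and the limits of what
synthetic recovery shows about real data.
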