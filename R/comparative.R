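#' Partition two peak sets by overlap
#'
#' Each region of set A is classified as shared (overlapping at least
#' `minOverlap` bp of some B region) or A-specific, and symmetrically
#' for B. Counts are directional: `nAandB` counts A regions overlapping
#' B, `nBandA` counts B regions overlapping A; the two may differ (one
#' region can overlap several on the other side).
#'
#' @param setA,setB GRanges on the same assembly.
#' @param minOverlap minimum shared bp to call an overlap (default 1).
#' @return a list with counts `nA`, `nB`, `nASpecific`, `nAandB`,
#'   `nBSpecific`, `nBandA` and the GRanges subsets `ASpecific`,
#'   `AandB`, `BSpecific`, `BandA`.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 199))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(199, 500), c(300, 600)))
#' overlapPartition(a, b)$nAandB
#' @export
overlapPartition <- function(setA, setB, minOverlap = 1L) {
  if (length(setA) == 0L || length(setB) == 0L)
    warning("empty peak set in overlap partition")
  a_shared <- countOverlaps(setA, setB, minoverlap = minOverlap) > 0
  b_shared <- countOverlaps(setB, setA, minoverlap = minOverlap) > 0
  list(nA = length(setA), nB = length(setB),
       nASpecific = sum(!a_shared), nAandB = sum(a_shared),
       nBSpecific = sum(!b_shared), nBandA = sum(b_shared),
       ASpecific = setA[!a_shared], AandB = setA[a_shared],
       BSpecific = setB[!b_shared], BandA = setB[b_shared])
}

#' Covered percentage of a target set by factor peak sets
#'
#' For each factor set, the fraction of target regions overlapped by at
#' least one factor region (>= `minOverlap` bp).
#'
#' @param targets GRanges of target regions (non-empty).
#' @param factorSets named list of GRanges.
#' @param minOverlap minimum shared bp (default 1).
#' @return data.frame with `factor_set`, `n_covered` and `fraction`
#'   (in \[0, 1\]).
#' @export
coveredPercentage <- function(targets, factorSets, minOverlap = 1L) {
  if (length(targets) == 0L) stop("empty target set")
  if (!length(factorSets)) stop("at least one factor set is required")
  if (is.null(names(factorSets)))
    names(factorSets) <- paste0("set", seq_along(factorSets))
  rows <- lapply(names(factorSets), function(nm) {
    nc <- sum(countOverlaps(targets, factorSets[[nm]],
                            minoverlap = minOverlap) > 0)
    data.frame(factor_set = nm, n_covered = nc,
               fraction = nc / length(targets), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired t-test on matched coverage fractions
#'
#' Standard paired t statistic on the per-factor differences d = x - y:
#' `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p from the t
#' distribution with n - 1 degrees of freedom. When the differences
#' have zero variance but nonzero mean the statistic is unbounded and p
#' is reported as the smallest positive double.
#'
#' @param x,y numeric vectors of matched fractions (same factors, same
#'   order), length >= 2.
#' @return a list with `meanDifference`, `t`, `df` and `p`.
#' @export
pairedDifferenceTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 matched pairs")
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md == 0) return(list(meanDifference = 0, t = 0, df = n - 1L, p = 1))
    return(list(meanDifference = md, t = sign(md) * Inf, df = n - 1L,
                p = .Machine$double.xmin))
  }
  tstat <- md / (s / sqrt(n))
  list(meanDifference = md, t = tstat, df = n - 1L,
       p = 2 * pt(-abs(tstat), df = n - 1L))
}

#' Motif enrichment within overlap subpopulations
#'
#' Runs [scanRegions()] + [enrichmentStats()] on each of the three
#' subpopulations of an overlap partition (A-specific, A-and-B,
#' B-specific) against one shared background region set, e.g. to ask
#' whether a response element concentrates in the co-bound fraction.
#'
#' @param partition result of [overlapPartition()].
#' @param psfm the [PSFM-class] to test.
#' @param genome named BStringSet of case-preserved sequences.
#' @param backgroundRegions GRanges scanned once for the background
#'   counts.
#' @param threshold similarity threshold (default 0.9, the convention
#'   for short, highly specific elements).
#' @param bothStrands scan both strands.
#' @return named list of [EnrichmentResult-class] for `ASpecific`,
#'   `AandB` and `BSpecific`; empty subpopulations are skipped with a
#'   warning.
#' @export
subpopulationMotifEnrichment <- function(partition, psfm, genome,
                                         backgroundRegions,
                                         threshold = 0.9,
                                         bothStrands = TRUE) {
  bg <- scanRegions(psfm, backgroundRegions, genome, threshold, bothStrands)
  subpops <- list(ASpecific = partition$ASpecific,
                  AandB = partition$AandB,
                  BSpecific = partition$BSpecific)
  out <- list()
  for (nm in names(subpops)) {
    if (length(subpops[[nm]]) == 0L) {
      warning("empty subpopulation skipped: ", nm)
      next
    }
    sc <- scanRegions(psfm, subpops[[nm]], genome, threshold, bothStrands)
    out[[nm]] <- enrichmentStats(sc$n, sc$lEff, bg$n, bg$lEff,
                                 motif = motifName(psfm))
  }
  out
}

#' Chromosome-level correlation of peak counts
#'
#' Per chromosome, counts peaks, distinct gene names and nucleotides
#' (chromosome length), and reports the squared Pearson correlation of
#' the peak counts against each. A factor binding mostly promoters
#' tracks gene counts; one binding uniformly tracks chromosome lengths.
#'
#' @param peaks GRanges of peaks.
#' @param genes gene GRanges (distinct `name` values are counted).
#' @param chromSizes named numeric of chromosome lengths (defines the
#'   chromosome universe; >= 3 required).
#' @return a list with `perChromosome` (data.frame: `chrom`, `n_peaks`,
#'   `n_genes`, `n_nucleotides`), `r2Gene` and `r2Nucleotide`.
#' @export
chromosomeCorrelation <- function(peaks, genes, chromSizes) {
  chroms <- names(chromSizes)
  if (length(chroms) < 3L) stop("need at least 3 chromosomes")
  pk <- table(factor(as.character(seqnames(peaks)), levels = chroms))
  gn <- vapply(chroms, function(ch) {
    length(unique(mcols(genes)$name[as.character(seqnames(genes)) == ch]))
  }, integer(1))
  df <- data.frame(chrom = chroms, n_peaks = as.integer(pk),
                   n_genes = as.integer(gn),
                   n_nucleotides = as.numeric(chromSizes),
                   stringsAsFactors = FALSE)
  if (var(df$n_peaks) == 0) stop("degenerate: zero variance in peak counts")
  list(perChromosome = df,
       r2Gene = cor(df$n_peaks, df$n_genes)^2,
       r2Nucleotide = cor(df$n_peaks, df$n_nucleotides)^2)
}
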