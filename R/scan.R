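`%||%` <- function(x, y) if (is.null(x)) y else x

# Integer-encode a raw (case-preserved) sequence: 1..4 for uppercase
# A/C/G/T, NA for everything else (soft-masked lowercase, N, gaps).
.encode_unmasked <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES)
}

# Sliding-window similarity over an encoded sequence for one weight
# matrix. Returns numeric vector of length (m - l + 1); windows touching
# any masked base are NA.
.window_scores <- function(code, w, denom) {
  l <- ncol(w)
  m <- length(code)
  n_win <- m - l + 1L
  if (n_win < 1L) return(numeric(0))
  num <- numeric(n_win)
  for (j in seq_len(l)) {
    wj <- w[, j][code[j:(j + n_win - 1L)]]  # NA codes give NA
    num <- num + wj
  }
  num / denom
}

#' Scan regions for motif matches
#'
#' Slides a window of the motif length with step 1 bp over each region
#' and scores every window with [similarityScore()]'s formula. A window
#' is scorable only if all its bases are unmasked (uppercase A/C/G/T);
#' soft-masked (lowercase) and `N` bases make a window unscorable. A
#' window is matched when S >= `threshold` on the forward strand or,
#' with `bothStrands`, on either strand; a window passing on both
#' strands is counted once, reporting the better strand. The effective
#' length is the number of unmasked bases across the regions (a base
#' count, not a window count), the denominator convention of the
#' repeat-masked enrichment statistics.
#'
#' @param psfm a [PSFM-class].
#' @param regions GRanges of regions to scan.
#' @param genome named BStringSet (or character vector) of
#'   case-preserved chromosome sequences, as from [readSequences()].
#' @param threshold similarity threshold in (0, 1]; matched means
#'   S >= threshold.
#' @param bothStrands scan both strands (default TRUE).
#' @return a list with elements
#'   \describe{
#'     \item{hits}{GRanges of matched windows (width = motif length)
#'       with metadata columns `similarity`, `region` (index into
#'       `regions`) and strand set to the better-scoring strand;}
#'     \item{n}{total matched-window count N;}
#'     \item{lEff}{effective (unmasked) length in bp across regions.}
#'   }
#' @examples
#' g <- Biostrings::BStringSet(c(chr1 = "TTTTTTTTTTGGAATTTTTT"))
#' pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 20))
#' scanRegions(consensusPSFM("GGAA"), pk, g, threshold = 1)$hits
#' @export
scanRegions <- function(psfm, regions, genome, threshold,
                        bothStrands = TRUE) {
  stopifnot(is(psfm, "PSFM"))
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]")
  if (is.character(genome)) genome <- BStringSet(genome)
  l <- length(psfm)
  sw_f <- .similarity_weights(psfm)
  sw_r <- .similarity_weights(reverseComplement(psfm))
  hit_chrom <- list(); hit_start <- list(); hit_strand <- list()
  hit_sim <- list(); hit_region <- list()
  n_total <- 0L
  l_eff <- 0
  for (i in seq_along(regions)) {
    ch <- as.character(seqnames(regions)[i])
    if (!ch %in% names(genome))
      stop("region on chromosome absent from genome: ", ch)
    if (end(regions)[i] > length(genome[[ch]]) || start(regions)[i] < 1L)
      stop("region ", i, " outside chromosome bounds")
    s <- as.character(subseq(genome[[ch]], start(regions)[i], end(regions)[i]))
    code <- .encode_unmasked(s)
    l_eff <- l_eff + sum(!is.na(code))
    if (length(code) < l) next
    sc_f <- .window_scores(code, sw_f$weights, sw_f$denom)
    sc <- sc_f
    strnd <- rep("+", length(sc_f))
    if (bothStrands) {
      sc_r <- .window_scores(code, sw_r$weights, sw_r$denom)
      better_r <- !is.na(sc_r) & (is.na(sc_f) | sc_r > sc_f)
      sc <- ifelse(better_r, sc_r, sc_f)
      strnd[better_r] <- "-"
    }
    matched <- which(!is.na(sc) & sc >= threshold)
    n_total <- n_total + length(matched)
    if (length(matched)) {
      k <- length(hit_chrom) + 1L
      hit_chrom[[k]] <- rep(ch, length(matched))
      hit_start[[k]] <- start(regions)[i] + matched - 1L
      hit_strand[[k]] <- strnd[matched]
      hit_sim[[k]] <- sc[matched]
      hit_region[[k]] <- rep(i, length(matched))
    }
  }
  st <- unlist(hit_start, use.names = FALSE)
  if (is.null(st)) st <- integer(0)
  hits <- GRanges(unlist(hit_chrom, use.names = FALSE) %||% character(0),
                  IRanges(st, st + l - 1L),
                  strand = unlist(hit_strand, use.names = FALSE) %||% character(0))
  mcols(hits)$similarity <- unlist(hit_sim, use.names = FALSE) %||% numeric(0)
  mcols(hits)$region <- unlist(hit_region, use.names = FALSE) %||% integer(0)
  list(hits = hits, n = n_total, lEff = l_eff)
}

#' Fold enrichment and Z-score of matched-window counts
#'
#' Under a binomial null, the matched count in a set of effective
#' length L is approximately normal with mean and variance both equal
#' to the expected count (the 1 - p term is dropped as p is small).
#' With N_c matches in a background of effective length L_c, the
#' expected sample count is `E = N_c * L_s / L_c`, the fold enrichment
#' `F = N_s / E` and the Z-score `Z = (N_s - E) / sqrt(E)`.
#'
#' @param nSample matched count in the sample set (N_s).
#' @param lSample effective sample length in bp (L_s), > 0.
#' @param nBackground matched count in the background set (N_c).
#' @param lBackground effective background length in bp (L_c), > 0.
#' @param motif optional motif label carried into the result.
#' @return an [EnrichmentResult-class]. When N_c = 0, F and Z are `NA`
#'   (undefined, not infinite); when E < 10 the `lowExpected` flag is
#'   set (normal approximation dubious).
#' @examples
#' enrichmentStats(9, 1e4, 100, 1e6)   # E = 1, F = 9, Z = 8
#' @export
enrichmentStats <- function(nSample, lSample, nBackground, lBackground,
                            motif = "") {
  vals <- c(nSample, lSample, nBackground, lBackground)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("counts and lengths must be finite and nonnegative")
  if (lSample <= 0 || lBackground <= 0)
    stop("effective lengths must be positive")
  E <- nBackground * lSample / lBackground
  if (nBackground == 0) {
    f <- NA_real_; z <- NA_real_
  } else {
    f <- nSample / E
    z <- (nSample - E) / sqrt(E)
  }
  new("EnrichmentResult", motif = motif,
      nSample = nSample, lSample = lSample,
      nBackground = nBackground, lBackground = lBackground,
      expected = E, foldEnrichment = f, zScore = z,
      lowExpected = E < 10)
}

#' Long / short-only / neither motif composition of a peak set
#'
#' A peak is motif-containing if it holds at least one matched window.
#' Peaks are classified hierarchically: first every peak with a match
#' to the long motif (at `thrLong`) is labelled `long`; among the
#' remaining peaks, those with a short-motif match (at `thrShort`) are
#' `short_only`; the rest are `neither`. The long class absorbs peaks
#' matching both motifs because the short element is nearly contained
#' in the long one. Defaults 0.8 (long) and 0.9 (short) trade
#' sensitivity against the long motif's lower per-position specificity.
#'
#' @param peaks GRanges of peak regions.
#' @param genome named BStringSet of case-preserved sequences.
#' @param psfmLong,psfmShort the two [PSFM-class] motifs.
#' @param thrLong,thrShort similarity thresholds.
#' @param bothStrands scan both strands.
#' @return a list of class `MotifComposition`: counts `nTotal`,
#'   `nLong`, `nShortOnly`, `nNeither`; percentages `pctLong`,
#'   `pctShortOnly`, `pctNeither` (summing to 100); and `class`, a
#'   factor of per-peak labels.
#' @export
motifComposition <- function(peaks, genome, psfmLong, psfmShort,
                             thrLong = 0.8, thrShort = 0.9,
                             bothStrands = TRUE) {
  if (length(peaks) == 0L) stop("empty peak set")
  long_scan <- scanRegions(psfmLong, peaks, genome, thrLong, bothStrands)
  short_scan <- scanRegions(psfmShort, peaks, genome, thrShort, bothStrands)
  has_long <- seq_along(peaks) %in% mcols(long_scan$hits)$region
  has_short <- seq_along(peaks) %in% mcols(short_scan$hits)$region
  cls <- ifelse(has_long, "long",
                ifelse(has_short, "short_only", "neither"))
  cls <- factor(cls, levels = c("long", "short_only", "neither"))
  n <- length(peaks)
  counts <- table(cls)
  out <- list(nTotal = n,
              nLong = unname(counts[["long"]]),
              nShortOnly = unname(counts[["short_only"]]),
              nNeither = unname(counts[["neither"]]),
              pctLong = unname(counts[["long"]]) / n * 100,
              pctShortOnly = unname(counts[["short_only"]]) / n * 100,
              pctNeither = unname(counts[["neither"]]) / n * 100,
              class = cls)
  class(out) <- "MotifComposition"
  out
}

#' @export
print.MotifComposition <- function(x, ...) {
  cat("Motif composition of", x$nTotal, "peaks\n")
  cat(sprintf("  long:       %d (%.1f%%)\n", x$nLong, x$pctLong))
  cat(sprintf("  short only: %d (%.1f%%)\n", x$nShortOnly, x$pctShortOnly))
  cat(sprintf("  neither:    %d (%.1f%%)\n", x$nNeither, x$pctNeither))
  invisible(x)
}

#' Distribution of motif hits relative to peak summits
#'
#' Offsets are computed as `floor(window start + l/2) - summit` (hit
#' midpoint relative to the summit, in bp) and binned over a symmetric
#' range. Peaks lacking a summit fall back to their midpoint, with a
#' warning.
#'
#' @param hits hit GRanges from [scanRegions()] (needs the `region`
#'   metadata column).
#' @param peaks the scanned peak GRanges with a `summit` metadata
#'   column.
#' @param breaks bin boundaries for the offsets (default 50-bp bins
#'   over +/- 500 bp). Offsets outside the range are dropped.
#' @return a list with `breaks`, `mids` and integer `counts` per bin.
#' @export
hitPositionDistribution <- function(hits, peaks,
                                    breaks = seq(-500, 500, by = 50)) {
  summit <- mcols(peaks)$summit
  if (is.null(summit)) summit <- rep(NA_real_, length(peaks))
  if (anyNA(summit)) {
    warning("peak(s) without summit: using region midpoint")
    mid <- floor((start(peaks) + end(peaks)) / 2)
    summit <- ifelse(is.na(summit), mid, summit)
  }
  counts <- integer(length(breaks) - 1L)
  if (length(hits)) {
    ridx <- mcols(hits)$region
    center <- floor(start(hits) + width(hits) / 2)
    off <- center - summit[ridx]
    inside <- off >= breaks[1L] & off <= breaks[length(breaks)]
    if (any(inside))
      counts <- as.integer(table(cut(off[inside], breaks,
                                     include.lowest = TRUE, right = FALSE)))
  }
  list(breaks = breaks,
       mids = (head(breaks, -1L) + breaks[-1L]) / 2,
       counts = counts)
}
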