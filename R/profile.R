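#' Summit anchors oriented by their linked genes
#'
#' Profiles are averaged 5'-to-3' in the orientation of the gene each
#' peak annotates to; distal intergenic peaks (no linked gene) are
#' arbitrarily taken to lie on the positive strand.
#'
#' @param annotations the `annotations` data.frame from
#'   [annotatePeaks()].
#' @return data.frame with `chrom`, `summit` and `orientation`
#'   (`"+"`/`"-"`), one row per peak.
#' @export
orientedAnchors <- function(annotations) {
  if (nrow(annotations) == 0L)
    return(data.frame(chrom = character(0), summit = numeric(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  ori <- ifelse(is.na(annotations$gene_strand), "+", annotations$gene_strand)
  data.frame(chrom = annotations$chrom, summit = annotations$anchor,
             orientation = ori, stringsAsFactors = FALSE)
}

#' Summit-aligned mean score profile
#'
#' Every anchor is expanded by `halfWidth` bp in each direction
#' (2 * halfWidth + 1 positions including the summit at relative
#' position 0); windows of minus-oriented anchors are reversed before
#' accumulation so all profiles read 5' to 3'. The per-position mean is
#' taken over anchors with a non-missing track value there: missing
#' scores are excluded from the mean, not imputed as zero (set
#' `missingAsZero = TRUE` for the alternative), since conservation
#' tracks have gaps and zero-imputation would bias profiles downward.
#' Anchors closer than `halfWidth` to a chromosome edge contribute only
#' their in-bounds positions.
#'
#' @param track score RleList from [readScoreTrack()]/[scoreTrack()].
#' @param anchors data.frame from [orientedAnchors()] (columns `chrom`,
#'   `summit`, `orientation`).
#' @param halfWidth expansion in bp on each side (default 3000).
#' @param missingAsZero impute missing track values as 0.
#' @return data.frame with `position` (-halfWidth..halfWidth), `mean`
#'   (NA where no anchor contributes) and `coverage` (number of anchors
#'   contributing a value).
#' @export
meanProfile <- function(track, anchors, halfWidth = 3000,
                        missingAsZero = FALSE) {
  stopifnot(halfWidth > 0)
  if (nrow(anchors) == 0L) stop("no anchors to profile")
  npos <- 2L * halfWidth + 1L
  total <- numeric(npos)
  coverage <- integer(npos)
  for (i in seq_len(nrow(anchors))) {
    pos <- (anchors$summit[i] - halfWidth):(anchors$summit[i] + halfWidth)
    vals <- trackValues(track, anchors$chrom[i], pos)
    if (identical(anchors$orientation[i], "-")) vals <- rev(vals)
    if (missingAsZero) vals[is.na(vals)] <- 0
    ok <- !is.na(vals)
    total[ok] <- total[ok] + vals[ok]
    coverage <- coverage + ok
  }
  data.frame(position = -halfWidth:halfWidth,
             mean = ifelse(coverage > 0, total / pmax(coverage, 1L), NA_real_),
             coverage = coverage)
}

#' Summit-aligned tag-density profile
#'
#' Tags (single-bp read 5' ends) are counted in windows of `window` bp
#' centered at positions stepping by `step` bp across
#' summit +/- `halfWidth`, normalized to tags per bp per anchor, and
#' averaged across anchors with the same 5'-to-3' orientation handling
#' as [meanProfile()].
#'
#' @param tags width-1 GRanges of tag positions (see [readTags()]).
#' @param anchors data.frame from [orientedAnchors()].
#' @param window counting window in bp (default 500).
#' @param halfWidth profile half-width in bp (default 3000).
#' @param step spacing of window centers in bp (default 10).
#' @return data.frame with `position`, `mean` (tags per bp per anchor)
#'   and `coverage` (= number of anchors).
#' @export
tagDensityProfile <- function(tags, anchors, window = 500,
                              halfWidth = 3000, step = 10) {
  stopifnot(halfWidth > 0, window > 0, step > 0)
  if (window > 2 * halfWidth)
    stop("window must not exceed 2 * halfWidth")
  if (nrow(anchors) == 0L) stop("no anchors to profile")
  offsets <- seq(-halfWidth, halfWidth, by = step)
  by_chrom <- split(start(tags), as.character(seqnames(tags)))
  by_chrom <- lapply(by_chrom, sort)
  half_lo <- floor(window / 2)
  total <- numeric(length(offsets))
  for (i in seq_len(nrow(anchors))) {
    centers <- if (identical(anchors$orientation[i], "-"))
      anchors$summit[i] - offsets else anchors$summit[i] + offsets
    pos <- by_chrom[[anchors$chrom[i]]]
    if (is.null(pos) || length(pos) == 0L) next
    lo <- centers - half_lo
    hi <- lo + window - 1
    cnt <- findInterval(hi, pos) - findInterval(lo - 1, pos)
    total <- total + cnt / window
  }
  data.frame(position = offsets,
             mean = total / nrow(anchors),
             coverage = rep(nrow(anchors), length(offsets)))
}
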