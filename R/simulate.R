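# All generators take an explicit seed and restore the caller's RNG
# state, so a fixed seed gives byte-identical output regardless of
# surrounding code.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Largest-remainder apportionment of n items into integer counts
# proportional to mix (so designed mixes are recovered exactly).
.apportion <- function(n, mix) {
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  setNames(as.integer(base), names(mix))
}

#' Generate a synthetic soft-masked genome
#'
#' I.i.d. bases at the requested GC content; a `maskedFraction` of each
#' chromosome is lowercased (soft-masked) in contiguous runs of
#' `runLength` bp, one per block of `round(runLength / maskedFraction)`
#' bp at a seeded random offset, so the realized masked share matches
#' the request up to block-remainder effects.
#'
#' @param nChroms number of chromosomes.
#' @param chromLength length of each chromosome in bp (>= 10 kb),
#'   recycled to `nChroms`.
#' @param gcFraction genomic GC content in \[0, 1).
#' @param maskedFraction soft-masked share in \[0, 1).
#' @param runLength masked run length in bp.
#' @param seed integer seed; the generator is a pure function of it.
#' @return list with `genome` (named BStringSet, chr1..chrN) and
#'   `truth` (parameters and chromosome lengths).
#' @export
generateGenome <- function(nChroms = 3, chromLength = 3e5,
                           gcFraction = 0.41, maskedFraction = 0.1,
                           runLength = 300, seed = 1) {
  if (gcFraction < 0 || gcFraction >= 1 || maskedFraction < 0 || maskedFraction >= 1)
    stop("fractions must lie in [0, 1)")
  chromLength <- rep_len(chromLength, nChroms)
  if (any(chromLength < 1e4)) stop("chromosome lengths must be >= 10 kb")
  .with_seed(seed, {
    prob <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
              G = gcFraction / 2, T = (1 - gcFraction) / 2)
    seqs <- vapply(seq_len(nChroms), function(i) {
      len <- chromLength[i]
      chars <- sample(DNA_BASES, len, replace = TRUE, prob = prob)
      if (maskedFraction > 0) {
        block <- max(runLength + 1L, round(runLength / maskedFraction))
        starts <- seq(1L, len - block + 1L, by = block)
        off <- sample.int(block - runLength + 1L, length(starts),
                          replace = TRUE) - 1L
        for (s in seq_along(starts)) {
          i0 <- starts[s] + off[s]
          idx <- i0:(i0 + runLength - 1L)
          chars[idx] <- tolower(chars[idx])
        }
      }
      paste(chars, collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(nChroms))
    list(genome = BStringSet(seqs),
         truth = list(seed = seed, gcFraction = gcFraction,
                      maskedFraction = maskedFraction,
                      chromLengths = setNames(chromLength, names(seqs))))
  })
}

#' Generate synthetic gene models
#'
#' Genes are placed one per fixed-size slot with >= 50 kb flanks, so
#' their promoter/enhancer windows never interleave and planted peak
#' categories are unambiguous under the priority rule. Strands are
#' random with both strands guaranteed when `nGenes >= 2`.
#'
#' @param genome output of [generateGenome()] (or a named BStringSet).
#' @param nGenes number of genes (errors when the genome has too few
#'   slots).
#' @param slot slot size in bp (default 150 kb).
#' @param geneLength min/max gene length in bp.
#' @param seed integer seed.
#' @return list with `genes` (GRanges with strand and `name`) and
#'   `truth` (TSS/TES/strand per gene).
#' @export
generateGeneModels <- function(genome, nGenes, slot = 150000,
                               geneLength = c(5000, 20000), seed = 1) {
  seqs <- if (is.list(genome)) genome$genome else genome
  lens <- setNames(vapply(seq_along(seqs), function(i) length(seqs[[i]]),
                          integer(1)), names(seqs))
  margin <- 55000
  slots <- list()
  for (ch in names(lens)) {
    n_slot <- floor((lens[[ch]] - 2 * margin) / slot)
    if (n_slot > 0)
      slots[[ch]] <- margin + slot * (seq_len(n_slot) - 1) + slot / 2
  }
  all_slots <- data.frame(
    chrom = rep(names(slots), lengths(slots)),
    center = unlist(slots, use.names = FALSE))
  if (nrow(all_slots) < nGenes)
    stop("genome too small: ", nrow(all_slots), " gene slots for ",
         nGenes, " genes")
  .with_seed(seed, {
    pick <- all_slots[seq_len(nGenes), , drop = FALSE]
    glen <- round(runif(nGenes, geneLength[1], geneLength[2]))
    strnd <- sample(c("+", "-"), nGenes, replace = TRUE)
    if (nGenes >= 2 && length(unique(strnd)) == 1L)
      strnd[1L] <- setdiff(c("+", "-"), strnd[1L])
    st <- round(pick$center - glen / 2)
    genes <- GRanges(pick$chrom, IRanges(st, st + glen - 1), strand = strnd)
    mcols(genes)$name <- sprintf("gene%03d", seq_len(nGenes))
    list(genes = genes,
         truth = list(seed = seed, name = mcols(genes)$name,
                      tss = tssPosition(genes), tes = tesPosition(genes),
                      strand = strnd))
  })
}

# Draw one motif instance. "consensus" picks a maximum-frequency letter
# per column (ties broken at random), guaranteeing S = 1; "sample"
# draws letters from the column frequencies.
.plant_instance <- function(psfm, mode = c("consensus", "sample")) {
  mode <- match.arg(mode)
  p <- profileMatrix(psfm)
  letters <- vapply(seq_len(ncol(p)), function(j) {
    if (mode == "consensus") {
      mx <- which(p[, j] >= max(p[, j]) - 1e-12)
      DNA_BASES[if (length(mx) > 1L) sample(mx, 1L) else mx]
    } else {
      sample(DNA_BASES, 1L, prob = p[, j])
    }
  }, character(1))
  paste(letters, collapse = "")
}

# Classify a single peak sequence as long / short_only / neither using
# the same windowed similarity as scanRegions (both strands).
.classify_sequence <- function(chars, psfmLong, psfmShort,
                               thrLong, thrShort) {
  code <- match(chars, DNA_BASES)
  has_hit <- function(psfm, thr) {
    if (length(code) < length(psfm)) return(FALSE)
    for (m in list(psfm, reverseComplement(psfm))) {
      sw <- .similarity_weights(m)
      sc <- .window_scores(code, sw$weights, sw$denom)
      if (any(!is.na(sc) & sc >= thr)) return(TRUE)
    }
    FALSE
  }
  if (has_hit(psfmLong, thrLong)) "long"
  else if (has_hit(psfmShort, thrShort)) "short_only"
  else "neither"
}

#' Generate peaks with planted categories and motifs
#'
#' Each peak is placed so that its summit falls in a demanded
#' annotation category (per [classifyAnchor()]'s rules) and carries a
#' demanded motif class: `long` peaks get a long-motif instance written
#' at the summit, `short_only` peaks a short-motif instance, `neither`
#' peaks nothing. Category and class counts follow the requested mixes
#' exactly (largest-remainder apportionment). Gene-linked peaks cycle
#' over the genes; distal intergenic peaks go > 50 kb from every
#' TSS/TES. Peaks are mutually disjoint (placement retries until an
#' unoccupied anchor is found).
#'
#' Background sequence under each peak is scrubbed: after planting, the
#' peak is re-classified at the stated thresholds and its background
#' bases resampled (up to `maxTries`) until the realized class equals
#' the planted one, so chance matches cannot blur the designed
#' composition.
#'
#' @param genome output of [generateGenome()] (modified copy returned).
#' @param genes gene GRanges from [generateGeneModels()].
#' @param nPeaks number of peaks.
#' @param categoryMix named fractions over the five annotation
#'   categories (summing to 1).
#' @param classMix named fractions over `long`, `short_only`,
#'   `neither`.
#' @param psfmLong,psfmShort motifs to plant.
#' @param thrLong,thrShort thresholds defining the classes (defaults
#'   0.8 / 0.9).
#' @param peakHalfWidth half-width of each peak region in bp.
#' @param plantMode `"consensus"` (exact-consensus planting, the
#'   default: composition recovery is then threshold-insensitive) or
#'   `"sample"` (instances drawn from the PSFM).
#' @param maxTries placement/scrub retry bound.
#' @param seed integer seed.
#' @return list with `peaks` (GRanges with `name`, `summit`, `fold`),
#'   `genome` (the modified genome, a list like [generateGenome()]'s)
#'   and `truth` (per-peak category, class, planted instance
#'   start/strand/motif, seed).
#' @export
generatePeaksWithMotifs <- function(genome, genes, nPeaks,
                                    categoryMix = c(promoter = 0.2,
                                                    gene_body = 0.2,
                                                    upstream_enhancer = 0.2,
                                                    downstream_enhancer = 0.2,
                                                    distal_intergenic = 0.2),
                                    classMix = c(long = 0.4,
                                                 short_only = 0.3,
                                                 neither = 0.3),
                                    psfmLong = defaultMotifs()$long,
                                    psfmShort = defaultMotifs()$short,
                                    thrLong = 0.8, thrShort = 0.9,
                                    peakHalfWidth = 150,
                                    plantMode = c("consensus", "sample"),
                                    maxTries = 50, seed = 1) {
  plantMode <- match.arg(plantMode)
  seqs <- if (is.list(genome)) genome$genome else genome
  if (abs(sum(categoryMix) - 1) > 1e-9) stop("categoryMix must sum to 1")
  if (abs(sum(classMix) - 1) > 1e-9) stop("classMix must sum to 1")
  categoryMix <- categoryMix[categoryMix > 0]
  bad <- setdiff(names(categoryMix), ANNOTATION_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  cat_counts <- .apportion(nPeaks, categoryMix)
  class_counts <- .apportion(nPeaks, classMix[c("long", "short_only", "neither")])
  n_linked <- sum(cat_counts[setdiff(names(cat_counts), "distal_intergenic")])
  if (n_linked > 0 && length(genes) == 0L)
    stop("gene-linked categories requested but no genes supplied")
  .with_seed(seed, {
    chars <- lapply(seq_along(seqs), function(i)
      strsplit(as.character(seqs[[i]]), "", fixed = TRUE)[[1L]])
    names(chars) <- names(seqs)
    lens <- vapply(chars, length, integer(1))

    # distal-intergenic allowed space: > 50 kb from every TSS and TES
    site_pos <- c(tssPosition(genes), tesPosition(genes))
    site_chr <- rep(as.character(seqnames(genes)), 2L)
    allowed <- lapply(names(lens), function(ch) {
      full <- IRanges(peakHalfWidth + 1L, lens[[ch]] - peakHalfWidth)
      sp <- site_pos[site_chr == ch]
      if (!length(sp)) return(full)
      forb <- IRanges::reduce(IRanges(sp - 50000, sp + 50000))
      IRanges::setdiff(full, forb)
    })
    names(allowed) <- names(lens)

    occupied <- lapply(names(lens), function(ch) IRanges())
    names(occupied) <- names(lens)
    is_free <- function(ch, lo, hi) {
      length(IRanges::findOverlaps(IRanges(lo, hi), occupied[[ch]])) == 0L
    }

    gene_order <- sample(length(genes))
    gene_ptr <- 0L
    categories <- rep(names(cat_counts), cat_counts)
    classes <- sample(rep(names(class_counts), class_counts))

    peak_chrom <- character(nPeaks); peak_summit <- integer(nPeaks)
    inst_start <- rep(NA_integer_, nPeaks)
    inst_strand <- rep(NA_character_, nPeaks)
    inst_seq <- rep(NA_character_, nPeaks)

    draw_anchor <- function(category) {
      if (category == "distal_intergenic") {
        for (tr in seq_len(maxTries)) {
          ch <- sample(names(lens), 1L,
                       prob = vapply(allowed, function(a) sum(IRanges::width(a)),
                                     numeric(1)))
          a <- allowed[[ch]]
          if (!length(a)) next
          iv <- sample(length(a), 1L, prob = IRanges::width(a))
          pos <- start(a)[iv] + sample.int(IRanges::width(a)[iv], 1L) - 1L
          if (is_free(ch, pos - peakHalfWidth, pos + peakHalfWidth))
            return(list(chrom = ch, anchor = pos))
        }
        stop("could not place distal intergenic peak: genome too crowded")
      }
      for (tr in seq_len(maxTries)) {
        gene_ptr <<- gene_ptr + 1L
        g <- genes[gene_order[(gene_ptr - 1L) %% length(genes) + 1L]]
        minus <- as.character(strand(g)) == "-"
        tss <- tssPosition(g); tes <- tesPosition(g)
        off <- switch(category,
          promoter = sample(-2000:1000, 1L),
          gene_body = sample(1001:(width(g) - 1L), 1L),
          upstream_enhancer = sample(seq(-40000L, -2001L), 1L),
          downstream_enhancer = NA_integer_)
        if (category == "downstream_enhancer") {
          t_off <- sample(1:40000, 1L)
          pos <- if (minus) tes - t_off else tes + t_off
        } else {
          pos <- if (minus) tss - off else tss + off
        }
        ch <- as.character(seqnames(g))
        if (pos - peakHalfWidth >= 1L && pos + peakHalfWidth <= lens[[ch]] &&
            is_free(ch, pos - peakHalfWidth, pos + peakHalfWidth))
          return(list(chrom = ch, anchor = pos))
      }
      stop("could not place peak in category ", category)
    }

    gc <- if (is.list(genome) && !is.null(genome$truth$gcFraction))
      genome$truth$gcFraction else 0.5
    bg_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

    for (i in seq_len(nPeaks)) {
      loc <- draw_anchor(categories[i])
      ch <- loc$chrom; smt <- loc$anchor
      lo <- smt - peakHalfWidth; hi <- smt + peakHalfWidth
      occupied[[ch]] <- c(occupied[[ch]], IRanges(lo, hi))
      peak_chrom[i] <- ch; peak_summit[i] <- smt

      plant <- function() {
        if (classes[i] == "neither") return(invisible(NULL))
        psfm <- if (classes[i] == "long") psfmLong else psfmShort
        inst <- .plant_instance(psfm, plantMode)
        strnd <- sample(c("+", "-"), 1L)
        if (strnd == "-")
          inst <- chartr("ACGT", "TGCA",
                         paste(rev(strsplit(inst, "")[[1L]]), collapse = ""))
        s0 <- smt - floor(nchar(inst) / 2)
        chars[[ch]][s0:(s0 + nchar(inst) - 1L)] <<-
          strsplit(inst, "", fixed = TRUE)[[1L]]
        inst_start[i] <<- s0; inst_strand[i] <<- strnd; inst_seq[i] <<- inst
      }
      plant()
      for (tr in seq_len(maxTries)) {
        got <- .classify_sequence(chars[[ch]][lo:hi], psfmLong, psfmShort,
                                  thrLong, thrShort)
        if (got == classes[i]) break
        if (tr == maxTries)
          stop("could not scrub peak ", i, " to class ", classes[i])
        chars[[ch]][lo:hi] <- sample(DNA_BASES, hi - lo + 1L,
                                     replace = TRUE, prob = bg_prob)
        plant()
      }
    }

    fold <- exp(rnorm(nPeaks, 3.2, 0.5))
    peaks <- GRanges(peak_chrom,
                     IRanges(peak_summit - peakHalfWidth,
                             peak_summit + peakHalfWidth))
    mcols(peaks)$name <- sprintf("peak%04d", seq_len(nPeaks))
    mcols(peaks)$summit <- peak_summit
    mcols(peaks)$fold <- fold
    new_seqs <- BStringSet(vapply(chars, paste, character(1), collapse = ""))
    names(new_seqs) <- names(seqs)
    out_genome <- if (is.list(genome)) {
      genome$genome <- new_seqs; genome
    } else list(genome = new_seqs, truth = NULL)
    list(peaks = peaks, genome = out_genome,
         truth = list(seed = seed, category = categories, class = classes,
                      instance_start = inst_start,
                      instance_strand = inst_strand,
                      instance_seq = inst_seq,
                      category_counts = cat_counts,
                      class_counts = class_counts))
  })
}

#' Generate a conservation-like score track with summit bumps
#'
#' Baseline everywhere, plus a symmetric triangular bump of the given
#' height and width centered at each anchor; overlapping bumps merge by
#' maximum. Deterministic given its inputs.
#'
#' @param anchors data.frame with `chrom` and `summit` columns.
#' @param chromLengths named chromosome lengths.
#' @param height bump height above baseline at the summit.
#' @param width full bump width in bp (< 6000 so a 3 kb half-width
#'   profile contains the whole bump).
#' @param baseline background score.
#' @return list with `track` (RleList) and `truth`.
#' @export
generateScoreTrack <- function(anchors, chromLengths, height = 0.9,
                               width = 1000, baseline = 0.1) {
  if (width >= 6000) stop("bump width must be < 6000 bp")
  w2 <- floor(width / 2)
  vecs <- lapply(names(chromLengths), function(ch)
    rep(baseline, chromLengths[[ch]]))
  names(vecs) <- names(chromLengths)
  if (nrow(anchors)) {
    for (i in seq_len(nrow(anchors))) {
      ch <- anchors$chrom[i]; smt <- anchors$summit[i]
      d <- max(1, smt - w2):min(chromLengths[[ch]], smt + w2)
      bump <- baseline + height * (1 - abs(d - smt) / w2)
      vecs[[ch]][d] <- pmax(vecs[[ch]][d], bump)
    }
  }
  track <- as(lapply(vecs, Rle), "RleList")
  list(track = track,
       truth = list(height = height, width = width, baseline = baseline,
                    nAnchors = nrow(anchors)))
}

#' Generate a co-bound second peak set with a designed overlap fraction
#'
#' Exactly `floor(overlapFraction * n)` of the `n` second-set regions
#' are placed to overlap (>= 1 bp) a distinct base peak, jittered
#' around its summit; the remainder are placed disjoint from every base
#' peak and from each other.
#'
#' @param basePeaks GRanges of the base set (needs `summit`).
#' @param chromLengths named chromosome lengths.
#' @param overlapFraction designed fraction in \[0, 1\].
#' @param n size of the second set (default `length(basePeaks)`).
#' @param jitter max summit displacement in bp of overlapping regions.
#' @param width second-set region width in bp.
#' @param maxTries placement retry bound (then errors: genome too
#'   crowded).
#' @param seed integer seed.
#' @return list with `peaks` (GRanges) and `truth` (`nOverlapping`,
#'   indices of the base peaks hit).
#' @export
generateCoboundSet <- function(basePeaks, chromLengths, overlapFraction,
                               n = length(basePeaks), jitter = 100,
                               width = 301, maxTries = 200, seed = 1) {
  if (overlapFraction < 0 || overlapFraction > 1)
    stop("overlapFraction must lie in [0, 1]")
  k <- floor(overlapFraction * n)
  w2 <- floor(width / 2)
  .with_seed(seed, {
    chosen <- if (k > 0) sample(length(basePeaks), k) else integer(0)
    summit <- mcols(basePeaks)$summit
    if (is.null(summit) || anyNA(summit))
      summit <- floor((start(basePeaks) + end(basePeaks)) / 2)
    lvls <- names(chromLengths)
    ov_chrom <- as.character(seqnames(basePeaks))[chosen]
    ov_center <- summit[chosen] + sample(-jitter:jitter, k, replace = TRUE)
    # clamp so the region still overlaps its base peak by >= 1 bp
    ov_center <- pmax(ov_center, start(basePeaks)[chosen] - w2)
    ov_center <- pmin(ov_center, end(basePeaks)[chosen] + w2)
    placed <- GRanges(factor(ov_chrom, levels = lvls),
                      IRanges(ov_center - w2, ov_center + w2))
    free_chrom <- character(n - k); free_start <- integer(n - k)
    for (j in seq_len(n - k)) {
      ok <- FALSE
      for (tr in seq_len(maxTries)) {
        ch <- sample(names(chromLengths), 1L,
                     prob = as.numeric(chromLengths))
        pos <- sample.int(chromLengths[[ch]] - width, 1L)
        cand <- GRanges(factor(ch, levels = lvls),
                        IRanges(pos, pos + width - 1L))
        if (length(findOverlaps(cand, basePeaks)) == 0L &&
            length(findOverlaps(cand, placed)) == 0L) {
          placed <- c(placed, cand)
          free_chrom[j] <- ch; free_start[j] <- pos
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("genome too crowded to place disjoint regions")
    }
    peaks <- placed
    mcols(peaks)$name <- sprintf("cob%04d", seq_len(n))
    mcols(peaks)$summit <- floor((start(peaks) + end(peaks)) / 2)
    mcols(peaks)$fold <- NA_real_
    list(peaks = peaks,
         truth = list(seed = seed, nOverlapping = k, baseIndex = chosen))
  })
}

#' Generate tag positions concentrated at peak summits
#'
#' Per peak, `tagsPerPeak` single-bp tag positions drawn from a normal
#' around the summit with the given spread, truncated (clamped) to
#' summit +/- 3 * spread; background tags are uniform over the genome.
#'
#' @param peaks GRanges with `summit`.
#' @param chromLengths named chromosome lengths.
#' @param tagsPerPeak tags per peak.
#' @param backgroundTags total uniform background tags.
#' @param spread standard deviation of the summit-centered draw in bp.
#' @param seed integer seed.
#' @return list with `tags` (width-1 GRanges) and `truth`.
#' @export
generateTags <- function(peaks, chromLengths, tagsPerPeak = 50,
                         backgroundTags = 0, spread = 100, seed = 1) {
  stopifnot(spread > 0)
  .with_seed(seed, {
    summit <- mcols(peaks)$summit
    if (is.null(summit) || anyNA(summit))
      summit <- floor((start(peaks) + end(peaks)) / 2)
    chrom <- rep(as.character(seqnames(peaks)), each = tagsPerPeak)
    ctr <- rep(summit, each = tagsPerPeak)
    pos <- round(rnorm(length(ctr), ctr, spread))
    pos <- pmax(pmin(pos, ctr + 3 * spread), ctr - 3 * spread)
    pos <- pmax(1, pmin(pos, chromLengths[chrom]))
    if (backgroundTags > 0) {
      bch <- sample(names(chromLengths), backgroundTags, replace = TRUE,
                    prob = as.numeric(chromLengths))
      bpos <- vapply(bch, function(ch) sample.int(chromLengths[[ch]], 1L),
                     integer(1))
      chrom <- c(chrom, bch); pos <- c(pos, unname(bpos))
    }
    tags <- GRanges(chrom, IRanges(pos, pos), strand = "+")
    list(tags = tags,
         truth = list(seed = seed, tagsPerPeak = tagsPerPeak,
                      backgroundTags = backgroundTags, spread = spread))
  })
}

#' Generate region sets with motif instances planted at a known density
#'
#' Builds a fresh random chromosome tiled with `nRegions` disjoint
#' regions and plants non-overlapping motif instances at an expected
#' `density` per unmasked bp (binomial count per region, uniform
#' placement), for enrichment-recovery experiments: scanning a
#' foreground set planted at `f * density` against a background planted
#' at `density` should recover a fold enrichment close to `f` up to
#' chance matches.
#'
#' @param nRegions number of regions.
#' @param regionWidth width of each region in bp.
#' @param density expected planted instances per bp.
#' @param psfm motif to plant.
#' @param plantMode `"consensus"` or `"sample"` (see
#'   [generatePeaksWithMotifs()]).
#' @param gcFraction background GC content.
#' @param gap unplanted spacer between regions in bp.
#' @param chromName chromosome name for the synthetic sequence.
#' @param seed integer seed.
#' @return list with `genome` (BStringSet of one chromosome), `regions`
#'   (GRanges) and `truth` (`nPlanted`, instance starts).
#' @export
generatePlantedDensitySet <- function(nRegions, regionWidth, density,
                                      psfm, plantMode = "consensus",
                                      gcFraction = 0.5, gap = 20,
                                      chromName = "sim", seed = 1) {
  l <- length(psfm)
  stopifnot(regionWidth > 2 * l)
  .with_seed(seed, {
    prob <- c((1 - gcFraction) / 2, gcFraction / 2, gcFraction / 2,
              (1 - gcFraction) / 2)
    total <- nRegions * (regionWidth + gap)
    chars <- sample(DNA_BASES, total, replace = TRUE, prob = prob)
    region_start <- (seq_len(nRegions) - 1L) * (regionWidth + gap) + 1L
    planted <- integer(0)
    for (r in seq_len(nRegions)) {
      n_inst <- rbinom(1L, regionWidth, density)
      if (n_inst == 0L) next
      used <- IRanges()
      for (m in seq_len(n_inst)) {
        for (tr in 1:50) {
          off <- sample.int(regionWidth - l + 1L, 1L)
          iv <- IRanges(off, off + l - 1L)
          if (length(IRanges::findOverlaps(iv, used)) == 0L) {
            used <- c(used, iv)
            s0 <- region_start[r] + off - 1L
            inst <- .plant_instance(psfm, plantMode)
            chars[s0:(s0 + l - 1L)] <- strsplit(inst, "", fixed = TRUE)[[1L]]
            planted <- c(planted, s0)
            break
          }
        }
      }
    }
    genome <- BStringSet(setNames(paste(chars, collapse = ""), chromName))
    regions <- GRanges(chromName,
                       IRanges(region_start,
                               region_start + regionWidth - 1L))
    list(genome = genome, regions = regions,
         truth = list(seed = seed, nPlanted = length(planted),
                      instanceStarts = planted, density = density))
  })
}
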