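test_that("regions shorter than the motif contribute no windows", {
  g <- make_genome(chr1 = "AAAA")
  r <- make_regions("chr1", 1, 4)
  res <- scanRegions(consensusPSFM("GGAAGG"), r, g, threshold = 0.8)
  expect_equal(res$n, 0L)
  expect_equal(length(res$hits), 0L)
  expect_equal(res$lEff, 4)
  empty <- scanRegions(consensusPSFM("GGAA"), r[0], g, threshold = 0.8)
  expect_equal(empty$n, 0L)
  expect_equal(empty$lEff, 0)
})

test_that("a planted consensus is found once at the right offset and strand", {
  seq <- paste0(strrep("T", 10), "GGAA", strrep("T", 10))
  g <- make_genome(chr1 = seq)
  r <- make_regions("chr1", 1, nchar(seq))
  res <- scanRegions(consensusPSFM("GGAA"), r, g, threshold = 1)
  expect_equal(res$n, 1L)
  expect_equal(start(res$hits), 11L)   # region start + offset 10
  expect_equal(as.character(strand(res$hits)), "+")
  expect_equal(mcols(res$hits)$similarity, 1)
})

test_that("reverse-complement instances are found on the minus strand", {
  seq <- paste0(strrep("C", 10), "TTCC", strrep("C", 10))  # revcomp of GGAA
  g <- make_genome(chr1 = seq)
  r <- make_regions("chr1", 1, nchar(seq))
  both <- scanRegions(consensusPSFM("GGAA"), r, g, threshold = 1,
                      bothStrands = TRUE)
  expect_equal(both$n, 1L)
  expect_equal(as.character(strand(both$hits)), "-")
  expect_equal(mcols(both$hits)$similarity, 1)
  fwd <- scanRegions(consensusPSFM("GGAA"), r, g, threshold = 1,
                     bothStrands = FALSE)
  expect_equal(fwd$n, 0L)
})

test_that("scanning a sequence equals scanning its reverse complement with the reverse-complemented PSFM", {
  set.seed(17)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  m <- random_psfm(5)
  g1 <- make_genome(chr1 = seq)
  g2 <- make_genome(chr1 = reverse_complement_chr(seq))
  r <- make_regions("chr1", 1, 400)
  a <- scanRegions(m, r, g1, threshold = 0.7)
  b <- scanRegions(reverseComplement(m), r, g2, threshold = 0.7)
  expect_equal(a$n, b$n)
  # mirrored window starts: start' = L - end + 1
  expect_setequal(401L - end(a$hits), start(b$hits))
})

test_that("masked bases are excluded from windows and effective length", {
  # 10 usable bases, 4 soft-masked, 4 N
  seq <- paste0("GGAA", "ggaa", "NNNN", "TTTTTT")
  g <- make_genome(chr1 = seq)
  r <- make_regions("chr1", 1, nchar(seq))
  res <- scanRegions(consensusPSFM("GGAA"), r, g, threshold = 1)
  expect_equal(res$lEff, 10)         # uppercase ACGT only
  expect_equal(res$n, 1L)            # masked copy not matched
  expect_equal(start(res$hits), 1L)
})

test_that("threshold-crossing counts match the brute-force oracle on all k-mers", {
  set.seed(41)
  for (rep in 1:3) {
    l <- 3
    m <- random_psfm(l)
    kmers <- all_kmers(l)
    seq <- paste(kmers, collapse = "")
    g <- make_genome(chr1 = seq)
    r <- make_regions("chr1", 1, nchar(seq))
    orac <- vapply(seq_len(nchar(seq) - l + 1), function(p) {
      w <- substr(seq, p, p + l - 1)
      max(oracle_similarity(profileMatrix(m), background(m), w),
          oracle_similarity(profileMatrix(m), background(m),
                            reverse_complement_chr(w)))
    }, numeric(1))
    for (thr in c(0.6, 0.8, 0.95)) {
      res <- scanRegions(m, r, g, threshold = thr)
      expect_equal(res$n, sum(orac >= thr))
    }
  }
})

test_that("enrichment statistics follow the printed formulas", {
  er <- enrichmentStats(9, 1e4, 100, 1e6)
  expect_equal(expectedCount(er), 1)
  expect_equal(foldEnrichment(er), 9)
  expect_equal(zScore(er), 8)
  expect_true(er@lowExpected)

  null <- enrichmentStats(100, 1e4, 100, 1e4)
  expect_equal(foldEnrichment(null), 1)
  expect_equal(zScore(null), 0)
  expect_false(null@lowExpected)

  none <- enrichmentStats(5, 1e4, 0, 1e6)
  expect_true(is.na(foldEnrichment(none)))
  expect_true(is.na(zScore(none)))

  expect_error(enrichmentStats(-1, 1e4, 1, 1e6), "nonnegative")
  expect_error(enrichmentStats(1, 0, 1, 1e6), "positive")
})

test_that("Z-scores are calibrated under the stated binomial null", {
  set.seed(97)
  ns <- rbinom(1000, 1e5, 1e-3)
  z <- vapply(ns, function(n) zScore(enrichmentStats(n, 1e5, 1000, 1e6)),
              numeric(1))
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(var(z), 0.85)
  expect_lt(var(z), 1.15)
})

test_that("composition partitions peaks and long absorbs both-motif peaks", {
  mo <- defaultMotifs()
  pad <- function(s) paste0(strrep("T", 20), s, strrep("T", 20))
  seqs <- c(
    p1 = pad("GAAAGAGGAAGTG"),                   # long only
    p2 = pad("AGAGGAAG"),                        # short only
    p3 = pad(paste0("AAAAGGGGAAGTG", strrep("C", 5), "AGAGGAAG")), # both
    p4 = pad("CCCCCCCC"))                        # neither
  g <- make_genome(chr1 = seqs[["p1"]], chr2 = seqs[["p2"]],
                   chr3 = seqs[["p3"]], chr4 = seqs[["p4"]])
  r <- GenomicRanges::GRanges(paste0("chr", 1:4),
                              IRanges::IRanges(1, nchar(seqs)))
  comp <- motifComposition(r, g, mo$long, mo$short)
  expect_equal(as.character(comp$class),
               c("long", "short_only", "long", "neither"))
  expect_equal(comp$nLong + comp$nShortOnly + comp$nNeither, comp$nTotal)
  expect_equal(comp$pctLong + comp$pctShortOnly + comp$pctNeither, 100)
  expect_error(motifComposition(r[0], g, mo$long, mo$short), "empty")
})

test_that("hit offsets are summit-relative with a flagged midpoint fallback", {
  seq <- paste0(strrep("T", 48), "GGAA", strrep("T", 48))
  g <- make_genome(chr1 = seq)
  r <- make_regions("chr1", 1, 100, summit = 51)
  res <- scanRegions(consensusPSFM("GGAA"), r, g, threshold = 1)
  h <- hitPositionDistribution(res$hits, r, breaks = seq(-50, 50, 10))
  expect_equal(sum(h$counts), 1L)
  # hit spans 49-52, center floor(49 + 2) = 51, offset 0 -> bin [0, 10)
  expect_equal(h$mids[which(h$counts == 1)], 5)
  # empty hits give an all-zero histogram
  h0 <- hitPositionDistribution(res$hits[0], r)
  expect_true(all(h0$counts == 0))
  # missing summit falls back to the midpoint with a warning
  r2 <- make_regions("chr1", 1, 100)
  expect_warning(hitPositionDistribution(res$hits, r2), "midpoint")
})
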