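test_that("genome generation is seed-deterministic with controlled GC and masking", {
  g1 <- generateGenome(nChroms = 2, chromLength = 5e4, gcFraction = 0.5,
                       maskedFraction = 0.2, seed = 9)
  g2 <- generateGenome(nChroms = 2, chromLength = 5e4, gcFraction = 0.5,
                       maskedFraction = 0.2, seed = 9)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  g3 <- generateGenome(nChroms = 2, chromLength = 5e4, gcFraction = 0.5,
                       maskedFraction = 0.2, seed = 10)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))

  big <- generateGenome(nChroms = 1, chromLength = 1e6, gcFraction = 0.5,
                        maskedFraction = 0, seed = 11)
  s <- strsplit(as.character(big$genome[[1]]), "")[[1]]
  gc <- mean(s %in% c("C", "G"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e6))

  masked <- generateGenome(nChroms = 1, chromLength = 1e5, gcFraction = 0.4,
                           maskedFraction = 0.2, seed = 12)
  sm <- strsplit(as.character(masked$genome[[1]]), "")[[1]]
  expect_lt(abs(mean(sm %in% c("a", "c", "g", "t")) - 0.2), 0.02)
  expect_error(generateGenome(gcFraction = 1.2), "fractions")
  expect_error(generateGenome(chromLength = 5000), "10 kb")
})

test_that("gene models fit their chromosomes with both strands and round-trip", {
  g <- generateGenome(nChroms = 2, chromLength = 1e6, seed = 21)
  gm <- generateGeneModels(g, 10, seed = 21)
  genes <- gm$genes
  expect_equal(length(genes), 10L)
  expect_setequal(unique(as.character(strand(genes))), c("+", "-"))
  lens <- setNames(rep(1e6, 2), paste0("chr", 1:2))
  expect_true(all(start(genes) >= 1))
  expect_true(all(end(genes) <= lens[as.character(seqnames(genes))]))
  # truth round-trips through the gene-model writer/reader
  f <- tempfile()
  writeGeneModels(genes, f)
  back <- readGeneModels(f)
  expect_equal(tssPosition(back), gm$truth$tss)
  expect_equal(tesPosition(back), gm$truth$tes)
  expect_error(generateGeneModels(g, 1000, seed = 1), "too small")
})

test_that("planted category and class mixes are recovered exactly downstream", {
  g <- generateGenome(nChroms = 3, chromLength = 1.2e6, seed = 31)
  gm <- generateGeneModels(g, 21, seed = 31)
  mix <- c(promoter = 0.14, gene_body = 0.42, upstream_enhancer = 0.165,
           downstream_enhancer = 0.099, distal_intergenic = 0.176)
  pk <- generatePeaksWithMotifs(g, gm$genes, 100, categoryMix = mix,
                                classMix = c(long = 0.4, short_only = 0.3,
                                             neither = 0.3), seed = 31)
  ann <- annotatePeaks(pk$peaks, gm$genes)
  got <- table(ann$annotations$category)
  expect_equal(as.integer(got[names(pk$truth$category_counts)]),
               as.integer(pk$truth$category_counts))
  mo <- defaultMotifs()
  comp <- motifComposition(pk$peaks, pk$genome$genome, mo$long, mo$short)
  expect_equal(comp$nLong, unname(pk$truth$class_counts[["long"]]))
  expect_equal(comp$nShortOnly, unname(pk$truth$class_counts[["short_only"]]))
  expect_equal(comp$nNeither, unname(pk$truth$class_counts[["neither"]]))
  # per-peak agreement, not just totals
  expect_equal(as.character(comp$class), pk$truth$class)
  # determinism
  pk2 <- generatePeaksWithMotifs(g, gm$genes, 100, categoryMix = mix,
                                 classMix = c(long = 0.4, short_only = 0.3,
                                              neither = 0.3), seed = 31)
  expect_identical(start(pk2$peaks), start(pk$peaks))
  expect_identical(as.character(pk2$genome$genome),
                   as.character(pk$genome$genome))
  expect_error(
    generatePeaksWithMotifs(g, gm$genes[0], 10,
                            categoryMix = c(promoter = 1), seed = 1),
    "no genes")
})

test_that("planted motif instances lie inside their peaks", {
  g <- generateGenome(nChroms = 2, chromLength = 1.2e6, seed = 41)
  gm <- generateGeneModels(g, 10, seed = 41)
  pk <- generatePeaksWithMotifs(g, gm$genes, 40, seed = 41)
  planted <- !is.na(pk$truth$instance_start)
  expect_true(all(pk$truth$instance_start[planted] >= start(pk$peaks)[planted]))
  expect_true(all(pk$truth$instance_start[planted] +
                    nchar(pk$truth$instance_seq[planted]) - 1 <=
                    end(pk$peaks)[planted]))
})

test_that("score-track bumps peak at the summit and merge by max", {
  cl <- c(chr1 = 50000)
  anc <- data.frame(chrom = "chr1", summit = 25000, orientation = "+")
  tr <- generateScoreTrack(anc, cl, height = 0.9, width = 1000,
                           baseline = 0.1)
  pr <- meanProfile(tr$track, anc, halfWidth = 1500)
  expect_equal(pr$mean[pr$position == 0], 1.0, tolerance = 1e-9)
  expect_equal(pr$mean[pr$position == 1200], 0.1)
  expect_equal(pr$position[which.max(pr$mean)], 0)
  # no anchors: flat baseline
  tr0 <- generateScoreTrack(anc[0, ], cl)
  expect_true(all(trackValues(tr0$track, "chr1", 1:100) == 0.1))
  # overlapping bumps merged by max stay bounded
  anc2 <- data.frame(chrom = "chr1", summit = c(25000, 25100),
                     orientation = "+")
  tr2 <- generateScoreTrack(anc2, cl)
  expect_lte(max(trackValues(tr2$track, "chr1", 24000:26000)), 1.0 + 1e-12)
})

test_that("cobound sets hit the designed overlap count exactly", {
  g <- generateGenome(nChroms = 3, chromLength = 1.2e6, seed = 51)
  gm <- generateGeneModels(g, 12, seed = 51)
  pk <- generatePeaksWithMotifs(g, gm$genes, 100, seed = 51)
  cl <- setNames(rep(1.2e6, 3), paste0("chr", 1:3))
  for (frac in c(0, 0.531, 1)) {
    cb <- generateCoboundSet(pk$peaks, cl, frac, seed = 52)
    op <- overlapPartition(pk$peaks, cb$peaks)
    expect_equal(op$nBandA, floor(frac * length(pk$peaks)))
    if (frac == 0) expect_equal(op$nBSpecific, length(cb$peaks))
    if (frac == 1) expect_equal(op$nBSpecific, 0L)
  }
  cb1 <- generateCoboundSet(pk$peaks, cl, 0.5, seed = 53)
  cb2 <- generateCoboundSet(pk$peaks, cl, 0.5, seed = 53)
  expect_identical(start(cb1$peaks), start(cb2$peaks))
})

test_that("tags concentrate at summits and respect the background switch", {
  g <- generateGenome(nChroms = 2, chromLength = 1.2e6, seed = 61)
  gm <- generateGeneModels(g, 8, seed = 61)
  pk <- generatePeaksWithMotifs(g, gm$genes, 30, seed = 61)
  cl <- setNames(rep(1.2e6, 2), paste0("chr", 1:2))
  tg <- generateTags(pk$peaks, cl, tagsPerPeak = 20, backgroundTags = 0,
                     spread = 100, seed = 62)
  expect_equal(length(tg$tags), 30L * 20L)
  # with no background, every tag is within 3 * spread of some summit
  summit <- mcols(pk$peaks)$summit
  per_chrom <- split(summit, as.character(seqnames(pk$peaks)))
  ok <- vapply(seq_along(tg$tags), function(i) {
    s <- per_chrom[[as.character(seqnames(tg$tags)[i])]]
    any(abs(start(tg$tags)[i] - s) <= 300)
  }, logical(1))
  expect_true(all(ok))
  tg2 <- generateTags(pk$peaks, cl, tagsPerPeak = 20, backgroundTags = 0,
                      spread = 100, seed = 62)
  expect_identical(start(tg$tags), start(tg2$tags))
})

test_that("planted-density sets recover the designed fold enrichment", {
  mo <- defaultMotifs()
  fg <- generatePlantedDensitySet(300, 500, 1e-3, mo$long, seed = 71,
                                  chromName = "fg")
  bg <- generatePlantedDensitySet(600, 1000, 2e-4, mo$long, seed = 72,
                                  chromName = "bg")
  genome <- c(fg$genome, bg$genome)
  s_fg <- scanRegions(mo$long, fg$regions, genome, 0.8)
  s_bg <- scanRegions(mo$long, bg$regions, genome, 0.8)
  er <- enrichmentStats(s_fg$n, s_fg$lEff, s_bg$n, s_bg$lEff)
  # chance hits measured on an unplanted run
  nul <- generatePlantedDensitySet(600, 1000, 0, mo$long, seed = 73,
                                   chromName = "nul")
  q <- scanRegions(mo$long, nul$regions, nul$genome, 0.8)$n / 6e5
  f_exp <- (1e-3 + q) / (2e-4 + q)
  se <- f_exp * sqrt(1 / (1e-3 * 150000) + 1 / (2e-4 * 600000))
  expect_lt(abs(foldEnrichment(er) - f_exp), 3 * se)
  expect_gt(zScore(er), 5)
})
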