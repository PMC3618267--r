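const_track <- function(len = 10000, value = 0.5, chrom = "chr1") {
  scoreTrack(GenomicRanges::GRanges(chrom, IRanges::IRanges(1, len),
                                    score = value),
             chromLengths = setNames(len, chrom))
}

test_that("a constant track gives a flat profile at the constant", {
  tr <- const_track()
  anc <- data.frame(chrom = "chr1", summit = c(3000, 5000, 7000),
                    orientation = c("+", "-", "+"))
  pr <- meanProfile(tr, anc, halfWidth = 500)
  expect_equal(nrow(pr), 1001L)
  expect_equal(pr$position, -500:500)
  expect_true(all(pr$mean == 0.5))
  expect_true(all(pr$coverage == 3L))
  expect_error(meanProfile(tr, anc[0, ], halfWidth = 500), "anchors")
})

test_that("minus orientation mirrors a linear gradient exactly", {
  len <- 5000
  tr <- scoreTrack(GenomicRanges::GRanges("chr1",
                                          IRanges::IRanges(1:len, 1:len),
                                          score = (1:len) / len),
                   chromLengths = c(chr1 = len))
  plus <- meanProfile(tr, data.frame(chrom = "chr1", summit = 2500,
                                     orientation = "+"), halfWidth = 200)
  minus <- meanProfile(tr, data.frame(chrom = "chr1", summit = 2500,
                                      orientation = "-"), halfWidth = 200)
  expect_equal(minus$mean, rev(plus$mean))
  # involution: flipping all orientations reverses the profile
  expect_equal(meanProfile(tr, data.frame(chrom = "chr1", summit = 2500,
                                          orientation = "+"),
                           halfWidth = 200)$mean,
               rev(minus$mean))
})

test_that("missing values are excluded from the mean, not imputed", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 200), c(100, 300)),
                               score = c(1, 3))
  tr <- scoreTrack(gr, chromLengths = c(chr1 = 400))
  anc <- data.frame(chrom = "chr1", summit = 150, orientation = "+")
  pr <- meanProfile(tr, anc, halfWidth = 60)
  expect_true(all(is.na(pr$mean[pr$position > -50 & pr$position < 50])))
  expect_equal(pr$coverage[pr$position == 0], 0L)
  expect_equal(pr$mean[pr$position == -55], 1)
  prz <- meanProfile(tr, anc, halfWidth = 60, missingAsZero = TRUE)
  expect_equal(prz$mean[prz$position == 0], 0)
})

test_that("profile means equal a brute-force per-position average", {
  set.seed(71)
  len <- 4000
  vals <- runif(len)
  vals[sample(len, 500)] <- NA
  tr <- scoreTrack(GenomicRanges::GRanges("chr1",
                                          IRanges::IRanges(which(!is.na(vals)),
                                                           which(!is.na(vals))),
                                          score = vals[!is.na(vals)]),
                   chromLengths = c(chr1 = len))
  anc <- data.frame(chrom = "chr1",
                    summit = sample(500:3500, 20),
                    orientation = sample(c("+", "-"), 20, replace = TRUE))
  W <- 100
  pr <- meanProfile(tr, anc, halfWidth = W)
  brute <- sapply(-W:W, function(p) {
    v <- vapply(seq_len(nrow(anc)), function(i) {
      pos <- if (anc$orientation[i] == "-") anc$summit[i] - p
             else anc$summit[i] + p
      vals[pos]
    }, numeric(1))
    c(mean(v[!is.na(v)]), sum(!is.na(v)))
  })
  expect_equal(pr$mean, unname(brute[1, ]), tolerance = 1e-12)
  expect_equal(pr$coverage, as.integer(brute[2, ]))
  # conservation of mass: sum(mean * coverage) equals total of values read
  expect_equal(sum(pr$mean * pr$coverage, na.rm = TRUE),
               sum(sapply(-W:W, function(p) {
                 v <- vapply(seq_len(nrow(anc)), function(i) {
                   pos <- if (anc$orientation[i] == "-") anc$summit[i] - p
                          else anc$summit[i] + p
                   vals[pos]
                 }, numeric(1))
                 sum(v, na.rm = TRUE)
               })), tolerance = 1e-9)
})

test_that("anchors near chromosome edges contribute in-bounds positions only", {
  tr <- const_track(len = 1000)
  pr <- meanProfile(tr, data.frame(chrom = "chr1", summit = 50,
                                   orientation = "+"), halfWidth = 100)
  # summit 50: profile position p reads chromosome position 50 + p,
  # valid only for p >= -49
  expect_equal(pr$coverage[pr$position == -49], 1L)
  expect_equal(pr$coverage[pr$position == -50], 0L)
  expect_true(is.na(pr$mean[pr$position == -100]))
})

test_that("tags at summits produce a central peak; density is linear in tags", {
  anc <- data.frame(chrom = "chr1", summit = c(10000, 20000, 30000),
                    orientation = "+")
  tags <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(rep(anc$summit, 5),
                                                  rep(anc$summit, 5)))
  td <- tagDensityProfile(tags, anc, window = 500, halfWidth = 2000,
                          step = 100)
  # every 500-bp window containing the summit ties at the maximum
  expect_equal(td$mean[td$position == 0], max(td$mean))
  expect_gt(td$mean[td$position == 0], 0)
  expect_true(all(td$mean[abs(td$position) > 1500] == 0))
  # doubling the tags doubles the profile
  td2 <- tagDensityProfile(c(tags, tags), anc, window = 500,
                           halfWidth = 2000, step = 100)
  expect_equal(td2$mean, 2 * td$mean)
  # zero tags: flat zero, not an error
  td0 <- tagDensityProfile(tags[0], anc, window = 500, halfWidth = 2000)
  expect_true(all(td0$mean == 0))
})

test_that("uniform tags give a flat density within binomial error", {
  set.seed(83)
  len <- 200000
  n <- 20000
  tags <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(sample(len, n, TRUE), width = 1))
  anc <- data.frame(chrom = "chr1", summit = seq(50000, 150000, by = 10000),
                    orientation = "+")
  td <- tagDensityProfile(tags, anc, window = 500, halfWidth = 3000,
                          step = 250)
  rate <- n / len
  se <- sqrt(rate / (500 * nrow(anc)))
  expect_true(all(abs(td$mean - rate) < 4 * se))
})

test_that("oriented anchors inherit gene strand with plus fallback", {
  ann <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                    anchor = c(100, 200, 300),
                    gene_strand = c("-", "+", NA),
                    stringsAsFactors = FALSE)
  anc <- orientedAnchors(ann)
  expect_equal(anc$orientation, c("-", "+", "+"))
  expect_equal(anc$summit, ann$anchor)
  expect_equal(nrow(orientedAnchors(ann[0, ])), 0L)
})
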