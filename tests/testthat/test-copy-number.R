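test_that("ploidy transform and its inverse match the worked examples", {
  expect_equal(ploidyOf(0), 2)
  expect_equal(round(ploidyOf(2.75), 1), 13.5)
  expect_equal(ploidyOf(-1), 1)
  expect_equal(round(lrrForCopies(10), 2), 2.32)
  expect_equal(lrrForCopies(2), 0)
  ## strictly increasing
  g <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(ploidyOf(g)) > 0))
  expect_equal(lrrForCopies(ploidyOf(1.3)), 1.3, tolerance = 1e-12)
})

test_that("normalization drops low-mappability bins and flattens GC bias", {
  set.seed(9)
  n <- 5000
  gc <- runif(n, 0.3, 0.6)
  bias <- 1 - 1.2 * (gc - 0.45)^2 / 0.0225      # known quadratic bias
  depthN <- rpois(n, 100 * pmax(bias, 0.3))
  depthT <- rpois(n, 100 * pmax(bias, 0.3))
  bins <- makeDepthBins(depthT, depthN, gc = gc)
  bins$mappability[1:50] <- 0.1
  out <- normalizeBins(bins)
  expect_equal(nrow(out), n - 50)
  expect_lt(abs(cor(out$normTumor, out$gc)), 0.05)
  expect_lt(abs(cor(out$normNormal, out$gc)), 0.05)
  ## median depth preserved
  expect_equal(median(out$normTumor), median(out$depthTumor),
               tolerance = 0.05)
})

test_that("normalization with flat GC is identity up to global scale", {
  bins <- makeDepthBins(rep(80L, 200), rep(100L, 200))
  out <- normalizeBins(bins)
  expect_equal(out$normTumor, bins$depthTumor)
  expect_equal(out$normNormal, bins$depthNormal)
  expect_error(normalizeBins(makeDepthBins(1, 1, mappability = 0.2)),
               "mappability")
})

test_that("log ratios follow the tumor/normal depth ratio", {
  bins <- makeDepthBins(c(100L, 200L, 673L), c(100L, 100L, 100L))
  bins <- normalizeBins(bins)
  out <- computeLrr(bins, center = FALSE)
  expect_equal(out$lrr[1], 0)
  expect_equal(out$lrr[2], 1)
  expect_equal(out$lrr[3], log2(6.73), tolerance = 1e-12)
  expect_equal(round(ploidyOf(log2(2^2.75)), 1), 13.5)
})

test_that("neutral-cluster centering anchors the diploid state at zero", {
  ## one quarter of the genome lost: the neutral three quarters define 0
  bins <- makeDepthBins(rep(c(100L, 50L), c(150, 50)), rep(100L, 200))
  out <- computeLrr(normalizeBins(bins))
  expect_equal(median(out$lrr[1:150]), 0)
  expect_equal(out$lrr[175], -1)
  ## gain-heavy genome: neutral bins still centre at zero, not below
  set.seed(44)
  lrrTruth <- rep(c(0, 0.3, 0, 0.3, 0, 0), each = 100)
  t2 <- rpois(600, 100 * 2^lrrTruth)
  n2 <- rpois(600, 100)
  b2 <- makeDepthBins(t2, n2,
                      chrom = rep(paste0("chr", 1:6), each = 100))
  out2 <- computeLrr(normalizeBins(b2))
  neutral <- lrrTruth == 0
  expect_lt(abs(mean(out2$lrr[neutral])), 0.02)
})

test_that("segmentation recovers noiseless breakpoints exactly with conserved means", {
  lrr <- rep(c(0, 1, -0.5), c(40, 25, 35))
  seg <- segmentProfile(makeLrrBins(lrr), nPerm = 200)
  expect_equal(length(seg), 3L)
  expect_equal(S4Vectors::mcols(seg)$nBins, c(40L, 25L, 35L))
  expect_equal(S4Vectors::mcols(seg)$lrr, c(0, 1, -0.5))
  ## conservation: total of bin lrrs equals segment-weighted total
  expect_equal(sum(S4Vectors::mcols(seg)$lrr * S4Vectors::mcols(seg)$nBins),
               sum(lrr))
})

test_that("a constant noisy profile stays a single segment per chromosome", {
  set.seed(3)
  bins <- rbind(makeLrrBins(rnorm(120, 0, 0.2), chrom = "chr1"),
                makeLrrBins(rnorm(80, 0, 0.2), chrom = "chr2"))
  seg <- segmentProfile(bins, nPerm = 400)
  expect_equal(length(seg), 2L)
})

test_that("noisy single-step breakpoint lands within 2 bins of the truth", {
  set.seed(21)
  for (rep in 1:5) {
    x <- c(rnorm(100, 0, 0.1), rnorm(100, 1, 0.1))
    seg <- segmentProfile(makeLrrBins(x), nPerm = 400)
    expect_equal(length(seg), 2L)
    expect_lte(abs(S4Vectors::mcols(seg)$nBins[1] - 100L), 2L)
  }
})

test_that("two implanted steps give three segments with accurate means", {
  set.seed(8)
  x <- c(rnorm(70, 0, 0.1), rnorm(60, 0.8, 0.1), rnorm(70, -0.6, 0.1))
  seg <- segmentProfile(makeLrrBins(x), nPerm = 400)
  expect_equal(length(seg), 3L)
  expect_equal(S4Vectors::mcols(seg)$lrr, c(0, 0.8, -0.6),
               tolerance = 0.05)
})

test_that("chosen split maximises RSS reduction (exhaustive oracle, <=50 bins)", {
  set.seed(14)
  for (i in 1:8) {
    n <- sample(20:50, 1)
    k0 <- sample(6:(n - 6), 1)
    x <- c(rnorm(k0, 0, 0.15), rnorm(n - k0, 1.2, 0.15))
    got <- rbscape:::bestSplit(x, 3L)$k
    expect_equal(got, oracleBestSplitRss(x, 3L))
  }
})

test_that("high-level amplification calls use a strict 2.32 cutoff", {
  lrr <- rep(c(0, 2.40, 0, 2.32, 0), c(20, 5, 20, 5, 20))
  seg <- segmentProfile(makeLrrBins(lrr), nPerm = 200)
  amp <- callHighLevelAmplifications(seg)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$lrr, 2.40)
  expect_gt(amp$ploidy, 10)            # 10.6 copies
})

test_that("equal-amplitude amplicons on one chromosome group as co-amplification", {
  lrr <- rep(c(0, 2.75, 0, 2.75, 0), c(15, 6, 15, 6, 15))
  seg <- segmentProfile(makeLrrBins(lrr), nPerm = 200)
  amp <- callHighLevelAmplifications(seg)
  expect_equal(nrow(amp), 2L)
  expect_equal(length(unique(amp$coAmpGroup)), 1L)
  ## genes attached from the genome model
  gm <- defaultGenomeModel()
  mycnLrr <- rep(0, 200)
  mycnLrr[40:46] <- 3.5               # bins covering the MYCN locus
  segM <- segmentProfile(makeLrrBins(mycnLrr, chrom = "chr2"), nPerm = 200)
  ampM <- callHighLevelAmplifications(segM, gm)
  expect_match(ampM$genes, "MYCN")
})

test_that("arm calls apply the 2.3 / 1.7 mean-ploidy thresholds", {
  arms <- data.frame(chrom = "chr1", arm = c("1p", "1q"),
                     start = c(1L, 2000001L), end = c(2000000L, 4000000L))
  mkSeg <- function(ploidy) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1L, 2000001L), c(2000000L, 4000000L)),
    nBins = c(100L, 100L), lrr = lrrForCopies(c(2, ploidy)),
    ploidy = c(2, ploidy))
  for (cs in list(c(2.0, "none"), c(1.65, "loss"), c(2.35, "gain"),
                  c(1.7, "none"), c(2.3, "none"))) {
    ac <- callArmEvents(mkSeg(as.numeric(cs[1])), arms)
    expect_equal(ac$status[ac$arm == "1q"], cs[2])
  }
})

test_that("arm mean ploidy is length-weighted and permutation-invariant", {
  arms <- data.frame(chrom = "chr1", arm = "1q", start = 1L, end = 400L)
  seg1 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1L, 301L), c(300L, 400L)),
    nBins = c(3L, 1L), lrr = c(0, 1), ploidy = c(2, 4))
  seg2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1L, 101L), c(100L, 400L)),
    nBins = c(1L, 3L), lrr = c(1, 0), ploidy = c(4, 2))
  m1 <- callArmEvents(seg1, arms)$meanPloidy
  m2 <- callArmEvents(seg2, arms)$meanPloidy
  expect_equal(m1, 2 * 0.75 + 4 * 0.25)
  expect_equal(m1, m2)
  ## uncovered arm
  armsX <- data.frame(chrom = "chr9", arm = "9q", start = 1L, end = 100L)
  expect_true(is.na(callArmEvents(seg1, armsX)$status))
})

test_that("chromothripsis flags oscillating profiles but not flat or focal ones", {
  osc <- rep(c(2, 1), 5)                 # 10 segments, 9 switches
  mkSeg <- function(ploidy, chrom = "chr13") {
    n <- length(ploidy)
    s <- seq(1L, by = 100000L, length.out = n)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + 99999L),
      nBins = rep(5L, n), lrr = lrrForCopies(ploidy), ploidy = ploidy)
  }
  expect_true(detectChromothripsis(mkSeg(osc))$chromothripsis)
  expect_false(detectChromothripsis(mkSeg(2))$chromothripsis)
  expect_false(detectChromothripsis(mkSeg(c(2, 0.1, 2)))$chromothripsis)
  ## mixed gains and losses oscillation
  expect_true(detectChromothripsis(mkSeg(rep(c(1, 3), 5)))$chromothripsis)
  ## locus report
  seg <- mkSeg(osc)
  loc <- GenomicRanges::GRanges("chr13", IRanges::IRanges(150000, 160000))
  out <- detectChromothripsis(seg, locus = loc)
  expect_true(out$locusAltered)         # second segment has state 1
})

test_that("gene recurrence scores match brute-force re-summation", {
  gm <- defaultGenomeModel()
  genes <- geneRanges(gm)
  set.seed(5)
  segs <- lapply(1:3, function(i) {
    lrr <- round(rnorm(12, 0, 0.8), 2)
    s <- seq(1L, by = 350000L, length.out = 12)
    GenomicRanges::GRanges(rep(c("chr13", "chr2"), each = 6),
      IRanges::IRanges(rep(s[1:6], 2), rep(s[1:6] + 349999L, 2)),
      nBins = rep(17L, 12), lrr = lrr, ploidy = ploidyOf(lrr))
  })
  out <- geneRecurrenceScore(segs, genes)
  ## brute force: per gene per tumor length-weighted overlap mean
  for (g in seq_along(genes)) {
    gs <- 0; ls <- 0; seen <- FALSE
    for (seg in segs) {
      hits <- GenomicRanges::findOverlaps(genes[g], seg)
      if (!length(hits)) next
      seen <- TRUE
      ov <- GenomicRanges::pintersect(
        rep(genes[g], length(hits)), seg[S4Vectors::subjectHits(hits)])
      w <- GenomicRanges::width(ov)
      m <- sum(S4Vectors::mcols(seg)$lrr[S4Vectors::subjectHits(hits)] *
                 w) / sum(w)
      if (m > 0) gs <- gs + m else ls <- ls + m
    }
    nm <- S4Vectors::mcols(genes)$gene[g]
    if (seen) {
      expect_equal(out$gainScore[out$gene == nm], gs)
      expect_equal(out$lossScore[out$gene == nm], ls)
    } else {
      expect_true(is.na(out$score[out$gene == nm]))
    }
  }
  ## neutral everywhere -> zero
  neutral <- GenomicRanges::GRanges("chr13",
    IRanges::IRanges(1, 4000000), nBins = 200L, lrr = 0, ploidy = 2)
  out0 <- geneRecurrenceScore(list(neutral), genes)
  expect_equal(out0$score[out0$gene == "RB1"], 0)
})

test_that("segment count burden matches the wild-type karyotype arithmetic", {
  mk <- function(n) GenomicRanges::GRanges(
    paste0("c", seq_len(n)), IRanges::IRanges(1, 100),
    nBins = 1L, lrr = 0, ploidy = 2)
  b <- segmentCountBurden(mk(24))
  expect_equal(b$count, 24L)
  expect_equal(round(b$log10Count, 2), 1.38)  # log10(24)
  ## an interstitial deletion adds two segments
  expect_equal(segmentCountBurden(mk(26))$count - 24L, 2L)
})

test_that("sex is estimated from the Y read fraction with QC on mismatch", {
  male <- c(chr1 = 1e6, chrX = 5e4, chrY = 2000)
  female <- c(chr1 = 1e6, chrX = 1e5, chrY = 90)
  expect_equal(estimateSex(male)$estimatedSex, "male")
  expect_equal(estimateSex(female)$estimatedSex, "female")
  flagged <- estimateSex(male, recordedSex = "female")
  expect_true(flagged$qcFlag)
  expect_false(estimateSex(male, recordedSex = "male")$qcFlag)
  expect_error(estimateSex(c(chr1 = 0, chrY = 0)), "zero")
})

test_that("SEG export writes the browser-compatible layout", {
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
                                nBins = 5L, lrr = 0.25, ploidy = 2.38)
  f <- withr::local_tempfile(fileext = ".seg")
  writeSeg(list(T01 = seg), f)
  out <- read.table(f, header = TRUE, sep = "\t")
  expect_named(out, c("ID", "chrom", "loc.start", "loc.end", "num.mark",
                      "seg.mean"))
  expect_equal(out$seg.mean, 0.25)
})
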