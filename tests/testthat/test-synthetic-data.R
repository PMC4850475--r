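test_that("cohort spec validates its fields", {
  expect_s4_class(CohortSpec(nTumors = 4, seed = 1), "CohortSpec")
  expect_error(CohortSpec(nTumors = 0), "positive")
  expect_error(CohortSpec(purityRange = c(0.5, 1.5)), "\\[0, 1\\]")
  expect_error(CohortSpec(purityRange = c(0.9, 0.5)), "ordered")
  expect_error(CohortSpec(binSize = -1), "binSize")
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  spec <- CohortSpec(nTumors = 3L, seed = 123L)
  a <- simulateCohort(spec)
  b <- simulateCohort(spec)
  expect_identical(a$variantTables, b$variantTables)
  expect_identical(a$binTables, b$binTables)
  expect_identical(a$bafTables, b$bafTables)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(truthTumors(a$groundTruth), truthTumors(b$groundTruth))
  c <- simulateCohort(CohortSpec(nTumors = 3L, seed = 124L))
  expect_false(identical(a$binTables, c$binTables))
})

test_that("expected VAFs follow the purity / copy-number closed form", {
  ## pure tumor, compound het: one mutated copy of two
  expect_equal(rbscape:::expectedVaf(1, 1, 1, 2), 0.5)
  ## pure tumor, homozygous after copy-neutral LOH
  expect_equal(rbscape:::expectedVaf(1, 1, 2, 2), 1)
  ## purity 0.96 halves through the mixture denominator
  expect_equal(rbscape:::expectedVaf(0.96, 1, 1, 2), 0.48)
  ## 16q one-copy loss at clonal fraction 1, purity 0.96: ploidy 1.04
  p <- 0.96
  mix <- p * (2 + 1 * -1) + (1 - p) * 2
  expect_equal(mix, 2 - 0.96)
})

test_that("simulated VAFs agree with the closed form within 3 standard errors", {
  spec <- CohortSpec(nTumors = 2L, purityRange = c(0.95, 0.95),
                     meanDepth = 100, seed = 9L)
  nSites <- 12000L
  set.seed(spec@seed)
  p <- 0.95
  expVaf <- rbscape:::expectedVaf(p, 1, 1, 2)
  depth <- rpois(nSites, spec@meanDepth)
  alt <- rbinom(nSites, depth, expVaf)
  v <- alt[depth > 0] / depth[depth > 0]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - expVaf), 3 * se)
})

test_that("per-bin expected depths integrate to the spec total depth", {
  spec <- CohortSpec(nTumors = 2L, seed = 31L)
  co <- simulateCohort(spec, dispersion = 1e-4, gcAmplitude = 0)
  bt <- co$binTables[[1]]
  ## a diploid normal with negligible noise and no GC bias averages to
  ## the spec mean depth
  expect_equal(mean(bt$depthNormal), spec@meanDepth, tolerance = 0.01)
})

test_that("implanted arm losses scale bin depth by the ploidy mixture", {
  spec <- CohortSpec(nTumors = 6L, purityRange = c(0.95, 0.95),
                     meanDepth = 1000, seed = 41L)
  co <- simulateCohort(spec, dispersion = 1e-4, gcAmplitude = 0)
  ev <- truthEvents(co$groundTruth)
  e16 <- ev[ev$region == "16q", ]
  expect_gt(nrow(e16), 0L)
  for (i in seq_len(nrow(e16))) {
    id <- e16$tumor[i]
    bt <- co$binTables[[id]]
    hit <- bt$chrom == "chr16" & bt$start >= e16$start[i]
    mixRatio <- mean(bt$depthTumor[hit]) / mean(bt$depthNormal[hit])
    expected <- (0.95 * (2 - e16$clonalFraction[i]) + 0.05 * 2) / 2
    expect_equal(mixRatio, expected, tolerance = 0.01)
  }
})

test_that("chromothripsis profiles alternate states and honour bounds", {
  set.seed(5)
  prof <- generateChromothripsisProfile("chr13", 10, "losses")
  expect_equal(nrow(prof), 10L)
  expect_setequal(unique(prof$state), c(1L, 2L))
  expect_true(all(diff(prof$state) != 0))       # strict alternation
  ## contiguity over the whole chromosome
  expect_equal(prof$start[-1], prof$end[-10] + 1L)

  mixed <- generateChromothripsisProfile("chr13", 12, "mixed")
  expect_true(any(mixed$state > 2) && any(mixed$state < 2))

  ## RB1 always falls in an altered segment on its chromosome
  gm <- defaultGenomeModel()
  rb1 <- gm$genes[gm$genes$gene == "RB1", ]
  for (i in 1:5) {
    pr <- generateChromothripsisProfile("chr13", sample(8:14, 1), "losses")
    seg <- pr[pr$start <= rb1$start & pr$end >= rb1$end, ]
    expect_equal(nrow(seg), 1L)
    expect_true(seg$state != 2L)
  }

  expect_error(generateChromothripsisProfile("chr13", 1), "at least 4")
  expect_error(generateChromothripsisProfile("chr13", 3), "at least 4")
  expect_error(generateChromothripsisProfile("chr13", 500), "exceeds")
  expect_error(generateChromothripsisProfile("chr99", 8), "unknown")
})

test_that("ground truth respects its invariants and modes", {
  spec <- CohortSpec(nTumors = 24L, seed = 61L)
  co <- simulateCohort(spec)
  gt <- co$groundTruth
  tt <- truthTumors(gt)
  expect_equal(nrow(tt), 24L)
  expect_true(all(tt$purity >= 0.9 & tt$purity <= 1))
  expect_true(all(tt$rb1Mode %in% rbscape:::rb1Modes()))
  ev <- truthEvents(gt)
  expect_true(all(ev$clonalFraction > 0 & ev$clonalFraction <= 1))
  ## chromothripsis only in tumors without another RB1 mechanism
  ct <- gt@chromothripsis
  if (nrow(ct))
    expect_true(all(tt$rb1Mode[match(ct$tumor, tt$id)] == "none"))
  ## phenotype table aligned with tumors
  expect_setequal(co$phenotypes$patient, tt$id)
})

test_that("a recorded-sex mismatch is reproduced for the QC path", {
  spec <- CohortSpec(nTumors = 4L, seed = 71L)
  co <- simulateCohort(spec, sexMismatch = "T02")
  tt <- truthTumors(co$groundTruth)
  rec <- co$phenotypes$sex[co$phenotypes$patient == "T02"]
  expect_false(rec == tt$sex[tt$id == "T02"])
})

test_that("viral read generation records truth counts and applies bounds", {
  refs <- makeViralReferences(nOtherViruses = 2L, seed = 3L)
  expect_named(refs$viral[1], "phiX_like")
  expect_equal(nchar(refs$viral[["phiX_like"]]), 5386L)

  out <- generateViralReads(refs, c(phiX_like = 1000L), seed = 5L)
  expect_equal(length(out$reads), 1000L)
  expect_equal(out$truth, data.frame(virus = "phiX_like", reads = 1000L))

  none <- generateViralReads(refs, c(phiX_like = 0L), seed = 5L)
  expect_equal(nrow(none$truth), 0L)
  expect_equal(length(none$reads), 0L)

  both <- generateViralReads(refs, c(phiX_like = 500L, virus_01 = 1L),
                             seed = 6L)
  expect_equal(sum(both$truth$reads), 501L)
  expect_equal(500 / 501, 0.998, tolerance = 5e-4)

  expect_error(generateViralReads(refs, c(phiX_like = -1L)))
  expect_error(generateViralReads(refs, c(phiX_like = 10L),
                                  readLength = 10000L), "readLength")
})

test_that("cohort artifacts serialize to plain-text formats and VCF round-trips", {
  spec <- CohortSpec(nTumors = 2L, seed = 81L)
  co <- simulateCohort(spec)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "T01_tumor.vcf")))
  expect_true(file.exists(file.path(dir, "T01_bins.tsv")))
  expect_true(file.exists(file.path(dir, "phenotypes.tsv")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(length(gt$tumors), 2L)
})
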