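test_that("phi coefficient handles perfect association and zero margins", {
  expect_equal(phiCoefficient(5, 0, 0, 5), 1)
  expect_equal(phiCoefficient(0, 5, 5, 0), -1)
  expect_true(is.na(phiCoefficient(0, 0, 3, 4)))   # empty first row
  expect_true(is.na(phiCoefficient(2, 3, 0, 0)))
})

test_that("phi equals Pearson correlation on all small 2x2 tables", {
  for (n11 in 0:4) for (n10 in 0:4) for (n01 in 0:4) for (n00 in 0:4) {
    a <- rep(c(1, 1, 0, 0), c(n11, n10, n01, n00))
    b <- rep(c(1, 0, 1, 0), c(n11, n10, n01, n00))
    phi <- phiCoefficient(n11, n10, n01, n00)
    if (is.na(phi)) {
      expect_true(length(a) < 2 || sd(a) == 0 || sd(b) == 0)
    } else {
      expect_equal(phi, cor(a, b), tolerance = 1e-12)
      ## symmetry in the two events
      expect_equal(phi, phiCoefficient(n11, n01, n10, n00))
    }
  }
})

test_that("event matrix assembles rows with thresholds and missingness", {
  tumors <- c("T1", "T2", "T3")
  snv <- data.frame(patient = c("T1", "T1"), gene = "RB1")
  arm <- data.frame(patient = tumors, arm = "16q",
                    status = c("loss", "none", NA))
  loh <- data.frame(patient = c("T1", "T2"), locus = "RB1",
                    loh = c(TRUE, FALSE))
  em <- buildEventMatrix(tumors, snvCalls = snv, armCalls = arm,
                         lohCalls = loh)
  m <- eventMatrix(em)
  expect_equal(m["RB1_snv", ], c(T1 = 1L, T2 = 0L, T3 = 0L))
  expect_equal(m["16q_scna", ], c(T1 = 1L, T2 = 0L, T3 = NA))
  expect_equal(m["RB1_loh", ], c(T1 = 1L, T2 = 0L, T3 = NA))
  expect_equal(dim(em), c(3L, 3L))
  expect_error(buildEventMatrix(tumors,
    snvCalls = data.frame(patient = "T9", gene = "RB1")), "unknown")
})

test_that("arm rows are altered on either side of the ploidy thresholds", {
  arm <- data.frame(patient = c("T1", "T2", "T3"), arm = "6p",
                    status = c("gain", "loss", "none"))
  m <- eventMatrix(buildEventMatrix(c("T1", "T2", "T3"), armCalls = arm))
  expect_equal(unname(m["6p_scna", ]), c(1L, 1L, 0L))
})

test_that("exclusivity testing matches the hypergeometric oracle with BH control", {
  ## perfectly exclusive implanted events in 40 tumors (20/20 split)
  m <- rbind(A = rep(c(1L, 0L), each = 20),
             B = rep(c(0L, 1L), each = 20))
  colnames(m) <- sprintf("T%02d", 1:40)
  out <- testMutualExclusivity(EventMatrix(m))
  expect_equal(nrow(out), 1L)
  expect_lt(out$phi, 0)
  expect_equal(out$direction, "exclusivity")
  expect_lt(out$qValue, 0.05)
  expect_equal(out$pValue, oracleFisherP(0, 20, 20, 0), tolerance = 1e-9)

  ## tiny cohorts lack power even at zero co-occurrence
  m4 <- rbind(A = c(1L, 1L, 0L, 0L), B = c(0L, 0L, 1L, 1L))
  colnames(m4) <- paste0("T", 1:4)
  expect_gt(testMutualExclusivity(EventMatrix(m4))$qValue, 0.05)
})

test_that("pairwise Fisher p-values agree with enumeration on random tables", {
  set.seed(61)
  for (i in 1:10) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value,
                 oracleFisherP(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("independent events keep the false discovery fraction at bay", {
  set.seed(71)
  hits <- 0L; pairs <- 0L
  for (r in 1:300) {
    m <- rbind(A = rbinom(40, 1, 0.4), B = rbinom(40, 1, 0.4))
    colnames(m) <- sprintf("T%02d", 1:40)
    out <- testMutualExclusivity(EventMatrix(m))
    if (!nrow(out)) next
    pairs <- pairs + nrow(out)
    hits <- hits + sum(out$qValue < 0.05)
  }
  expect_lte(hits / pairs, 0.05)
})

test_that("missing entries are handled by complete cases only", {
  m <- rbind(A = c(1L, 1L, 0L, 0L, NA, 1L),
             B = c(0L, 0L, 1L, 1L, 1L, NA))
  colnames(m) <- paste0("T", 1:6)
  out <- testMutualExclusivity(EventMatrix(m))
  expect_equal(out$n, 4L)
  expect_equal(out$n11 + out$n10 + out$n01 + out$n00, 4L)
})

test_that("q-values are monotone in p-value rank and never below p", {
  set.seed(81)
  m <- matrix(rbinom(8 * 30, 1, 0.5), nrow = 8,
              dimnames = list(paste0("E", 1:8), paste0("T", 1:30)))
  out <- testMutualExclusivity(EventMatrix(m))
  ord <- order(out$pValue)
  expect_true(all(diff(out$qValue[ord]) >= -1e-12))
  expect_true(all(out$qValue >= out$pValue - 1e-12))
  expect_equal(out$qValue, p.adjust(out$pValue, "BH")[order(
    order(out$qValue, out$pValue))], tolerance = 1e-12)
})

test_that("an event confined to the older half shows an age association", {
  age <- c(seq(10, 29), seq(40, 59))
  ev <- as.integer(age >= 40)
  m <- matrix(ev, nrow = 1, dimnames = list("arm_event",
                                            sprintf("T%02d", 1:40)))
  ph <- data.frame(patient = sprintf("T%02d", 1:40), ageMonths = age)
  out <- testPhenotypeAssociations(EventMatrix(m), ph)
  expect_lt(out$qValue, 0.01)
  expect_equal(out$direction, "higher")
  expect_equal(out$test, "ranksum")
})

test_that("an event identical to a categorical label is perfectly associated", {
  heredity <- rep(c("heritable", "non_heritable"), each = 10)
  m <- matrix(as.integer(heredity == "heritable"), nrow = 1,
              dimnames = list("germline_rb1", paste0("T", 1:20)))
  ph <- data.frame(patient = paste0("T", 1:20), heredity = heredity)
  out <- testPhenotypeAssociations(EventMatrix(m), ph)
  expect_equal(out$test, "fisher")
  expect_lt(out$pValue, 1e-4)
})

test_that("null phenotype associations yield roughly uniform p-values", {
  set.seed(15)
  ps <- replicate(200, {
    m <- matrix(rbinom(20, 1, 0.5), nrow = 1,
                dimnames = list("E", paste0("T", 1:20)))
    ph <- data.frame(patient = paste0("T", 1:20), ageMonths = rnorm(20))
    out <- testPhenotypeAssociations(EventMatrix(m), ph)
    if (nrow(out)) out$pValue else NA_real_
  })
  ps <- ps[!is.na(ps)]
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  ## constant phenotypes are skipped
  m <- matrix(c(1L, 0L), nrow = 1, dimnames = list("E", c("T1", "T2")))
  ph <- data.frame(patient = c("T1", "T2"), ageMonths = c(5, 5))
  expect_equal(nrow(testPhenotypeAssociations(EventMatrix(m), ph)), 0L)
})

test_that("event matrices round-trip through TSV including missing entries", {
  m <- rbind(A = c(1L, 0L, NA), B = c(NA, 1L, 0L))
  colnames(m) <- paste0("T", 1:3)
  em <- EventMatrix(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEventMatrix(em, f)
  back <- readEventMatrix(f)
  expect_identical(eventMatrix(back), eventMatrix(em))
})

test_that("event matrix validity rejects non-binary entries", {
  m <- matrix(c(0L, 2L), nrow = 1,
              dimnames = list("E", c("T1", "T2")))
  expect_error(EventMatrix(m), "0, 1 or NA")
})
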