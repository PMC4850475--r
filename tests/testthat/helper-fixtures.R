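# Builders for small in-code fixtures shared across test files.

# A variant table row with sensible defaults; override any field.
makeVariant <- function(..., patient = "T01", chrom = "chr13",
                        pos = 2450000L, ref = "C", alt = "T",
                        genotypeClass = "AB", depth = 50L, altDepth = 25L,
                        qual = 500, fs = 5, filterFlag = "PASS",
                        popFreqEsp = 0, popFreq1kg = 0,
                        consequence = "stopgain",
                        pred1 = "pathogenic", pred2 = "pathogenic",
                        pred3 = "benign", pred4 = "benign", gene = "RB1") {
  df <- data.frame(patient = patient, chrom = chrom, pos = pos, ref = ref,
                   alt = alt, genotypeClass = genotypeClass, depth = depth,
                   altDepth = altDepth, qual = qual, fs = fs,
                   filterFlag = filterFlag, popFreqEsp = popFreqEsp,
                   popFreq1kg = popFreq1kg, consequence = consequence,
                   pred1 = pred1, pred2 = pred2, pred3 = pred3,
                   pred4 = pred4, gene = gene, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

makeVariants <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Bin table for one synthetic chromosome profile: lrr given per bin.
makeLrrBins <- function(lrr, chrom = "chr1", binSize = 20000L) {
  n <- length(lrr)
  start <- seq(1L, by = binSize, length.out = n)
  data.frame(chrom = chrom, start = start, end = start + binSize - 1L,
             lrr = lrr, stringsAsFactors = FALSE)
}

# Raw depth bins (for normalizeBins/computeLrr tests).
makeDepthBins <- function(depthTumor, depthNormal,
                          gc = rep(0.45, length(depthTumor)),
                          mappability = rep(1, length(depthTumor)),
                          chrom = "chr1", binSize = 20000L) {
  n <- length(depthTumor)
  start <- seq(1L, by = binSize, length.out = n)
  data.frame(chrom = chrom, start = start, end = start + binSize - 1L,
             gc = gc, mappability = mappability,
             depthTumor = depthTumor, depthNormal = depthNormal,
             stringsAsFactors = FALSE)
}

# Marker table for one sample.
makeMarkers <- function(baf, chrom = "chr13", spacing = 20000L,
                        depth = 100L, sample = "T01") {
  n <- length(baf)
  data.frame(sample = sample, chrom = chrom,
             pos = seq(10000L, by = spacing, length.out = n),
             depth = depth, baf = baf, genotypeNormal = "AB",
             stringsAsFactors = FALSE)
}

# Exhaustive single-split scan minimising the residual sum of squares;
# independent oracle for segmentation breakpoint placement.
oracleBestSplitRss <- function(x, minBins = 3L) {
  n <- length(x)
  best <- list(rss = Inf, k = NA_integer_)
  for (k in seq.int(minBins, n - minBins)) {
    left <- x[1:k]; right <- x[(k + 1):n]
    rss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (rss < best$rss) best <- list(rss = rss, k = k)
  }
  best$k
}

# Fisher exact two-sided p-value by direct hypergeometric enumeration.
oracleFisherP <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10; c1 <- n11 + n01; n <- n11 + n10 + n01 + n00
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(k)
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)),
    numeric(1))
  pObs <- probs[match(n11, support)]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Kendall tau by exhaustive concordant/discordant pair counting (no ties).
oracleKendallTau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}
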