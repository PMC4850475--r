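## Recursive binary segmentation of a numeric series with a permutation
## test on the maximal two-sample t statistic.  Used for per-chromosome
## log2-ratio profiles and (via segmentMbaf) for mirrored-BAF series.

## Best single split of x honouring a minimum leaf size.  The statistic at
## boundary k is the larger of (a) the global prefix/suffix mean contrast
## |m1 - m2| / sqrt(1/n1 + 1/n2) — monotone in the between-group sum of
## squares, so for a single-step signal its argmax coincides with the
## residual-sum-of-squares-minimising split — and (b) the same contrast
## computed over a bounded window either side of k.
## Robust per-series noise scale: median absolute successive difference,
## scaled to sd under normality.  Estimated from the series itself (and
## re-estimated on every permuted series), so segments that carry real
## structure are not penalised by their own signal variance.
noiseScale <- function(x) {
  s <- median(abs(diff(x))) / 0.954
  if (s <= 0) s <- max(sd(x) * 1e-3, .Machine$double.eps)
  s
}

bestSplit <- function(x, minBins, localWindow = 10L) {
  n <- length(x)
  if (n < 2L * minBins) return(list(stat = -Inf, k = NA_integer_))
  cs <- cumsum(x)
  total <- cs[n]
  k <- seq.int(minBins, n - minBins)
  m1 <- cs[k] / k
  m2 <- (total - cs[k]) / (n - k)
  stat <- abs(m1 - m2) / sqrt(1 / k + 1 / (n - k))
  ## multi-scale local moving-window contrast at the same boundaries:
  ## oscillating profiles (chromothripsis) have flat global means but
  ## sharp local steps, which the prefix statistic alone cannot see; a
  ## window matched to the block width maximises the contrast
  cs0 <- c(0, cs)
  for (w in unique(pmin(localWindow, c(3L, 5L, localWindow)))) {
    w1 <- pmin(k, w)
    w2 <- pmin(n - k, w)
    l1 <- (cs[k] - cs0[k - w1 + 1L]) / w1
    l2 <- (c(cs, total)[k + w2] - cs[k]) / w2
    local <- abs(l1 - l2) / sqrt(1 / w1 + 1 / w2)
    stat <- pmax(stat, local)
  } / noiseScale(x)
  i <- which.max(stat)
  list(stat = stat[i], k = k[i])
}

## Permutation p-value for the observed best-split statistic.  When
## stopAt is given, the scan aborts (returning a value >= stopAt) as soon
## as the exceedance count makes a p-value below stopAt impossible.
splitPvalue <- function(x, observed, minBins, nPerm, stopAt = NULL) {
  if (!is.finite(observed)) return(1)
  bail <- if (is.null(stopAt)) Inf else stopAt * (nPerm + 1L) - 1L
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    if (bestSplit(sample(x), minBins)$stat >= observed) {
      exceed <- exceed + 1L
      if (exceed > bail) return((exceed + 1L) / (i + 1L))
    }
  }
  (exceed + 1L) / (nPerm + 1L)
}

## Best interior window [i, j] against its complement (the circular-style
## statistic).  Needed for oscillating profiles, where the two halves of
## any prefix split have similar means and the prefix statistic is blind.
bestArc <- function(x, minBins) {
  n <- length(x)
  if (n < 3L * minBins) return(list(stat = -Inf, i = NA, j = NA))
  cs <- c(0, cumsum(x))
  total <- cs[n + 1L]
  best <- list(stat = -Inf, i = NA_integer_, j = NA_integer_)
  for (L in seq.int(minBins, n - 2L * minBins)) {
    i <- seq.int(minBins + 1L, n - L - minBins + 1L)
    if (!length(i)) next
    sumIn <- cs[i + L] - cs[i]
    mIn <- sumIn / L
    mOut <- (total - sumIn) / (n - L)
    stat <- abs(mIn - mOut) / sqrt(1 / L + 1 / (n - L))
    w <- which.max(stat)
    if (stat[w] > best$stat)
      best <- list(stat = stat[w], i = i[w], j = i[w] + L - 1L)
  }
  best$stat <- best$stat / noiseScale(x)
  best
}

arcPvalue <- function(x, observed, minBins, nPerm, stopAt = NULL) {
  if (!is.finite(observed)) return(1)
  bail <- if (is.null(stopAt)) Inf else stopAt * (nPerm + 1L) - 1L
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    if (bestArc(sample(x), minBins)$stat >= observed) {
      exceed <- exceed + 1L
      if (exceed > bail) return((exceed + 1L) / (i + 1L))
    }
  }
  (exceed + 1L) / (nPerm + 1L)
}

## Recursive splitter; returns integer vector of segment lengths.
## A prefix (binary) split is tried first; when it is not significant, an
## interior-window split is tried before declaring the segment flat.
segmentSeries <- function(x, alpha = 0.01, minBins = 3L, nPerm = 1000L) {
  n <- length(x)
  if (n < 2L * minBins) return(n)
  sp <- bestSplit(x, minBins)
  if (is.finite(sp$stat)) {
    p <- splitPvalue(x, sp$stat, minBins, nPerm, stopAt = alpha)
    if (p < alpha) {
      return(c(segmentSeries(x[seq_len(sp$k)], alpha, minBins, nPerm),
               segmentSeries(x[(sp$k + 1L):n], alpha, minBins, nPerm)))
    }
  }
  arc <- bestArc(x, minBins)
  if (is.finite(arc$stat)) {
    p <- arcPvalue(x, arc$stat, minBins, nPerm, stopAt = alpha)
    if (p < alpha) {
      return(c(segmentSeries(x[seq_len(arc$i - 1L)], alpha, minBins, nPerm),
               segmentSeries(x[arc$i:arc$j], alpha, minBins, nPerm),
               segmentSeries(x[(arc$j + 1L):n], alpha, minBins, nPerm)))
    }
  }
  n
}

#' Segment a binned log2-ratio profile into piecewise-constant segments
#'
#' Recursive binary segmentation: within each chromosome the split
#' maximising a two-sample t statistic is accepted when its permutation
#' p-value falls below `alpha`, and both halves are segmented recursively.
#' Segment log2-ratios are the means of their member bins, and local ploidy
#' is derived under a diploid reference as `2 * 2^lrr`.
#'
#' @param bins data.frame of bins with columns `chrom`, `start`, `end` and
#'   `lrr` (see [computeLrr()]); rows must be position-sorted within
#'   chromosome.
#' @param alpha Permutation p-value threshold for accepting a split
#'   (default 0.01).
#' @param minBins Minimum bins per segment (default 3).
#' @param nPerm Number of permutations per tested split (default 1000).
#' @return A [GenomicRanges::GRanges] of segments with metadata columns
#'   `nBins`, `lrr` and `ploidy`, ordered and non-overlapping within
#'   chromosome.
#' @seealso [ploidyOf()], [segmentCountBurden()]
#' @export
segmentProfile <- function(bins, alpha = 0.01, minBins = 3L, nPerm = 1000L) {
  stopifnot(all(c("chrom", "start", "end", "lrr") %in% names(bins)))
  bins <- bins[is.finite(bins$lrr), , drop = FALSE]
  if (!nrow(bins)) stop("no bins with finite log2-ratios")
  out <- lapply(unique(bins$chrom), function(ch) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    lens <- segmentSeries(b$lrr, alpha = alpha, minBins = minBins,
                          nPerm = nPerm)
    endIdx <- cumsum(lens)
    startIdx <- c(1L, head(endIdx, -1L) + 1L)
    data.frame(
      chrom = ch,
      start = b$start[startIdx],
      end = b$end[endIdx],
      nBins = as.integer(lens),
      lrr = vapply(seq_along(lens), function(i)
        mean(b$lrr[startIdx[i]:endIdx[i]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  seg <- do.call(rbind, out)
  GenomicRanges::GRanges(
    seg$chrom, IRanges::IRanges(seg$start, seg$end),
    nBins = seg$nBins, lrr = seg$lrr, ploidy = ploidyOf(seg$lrr)
  )
}
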