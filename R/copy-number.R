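#' Local ploidy from a log2 ratio under a diploid reference
#'
#' Total DNA copy number of a region whose normalized tumor/normal depth
#' ratio is `2^lrr`, anchored at two copies for `lrr = 0`:
#' `ploidy = 2 * 2^lrr`.  A segment with log2-ratio 2.75 therefore carries
#' 13.5 copies.
#'
#' @param lrr Numeric log2 ratio(s).
#' @return Numeric copy number(s), strictly increasing in `lrr`.
#' @examples
#' ploidyOf(0)     # 2
#' ploidyOf(2.75)  # 13.45 -> 13.5 copies
#' @export
ploidyOf <- function(lrr) 2 * 2^lrr

#' Log2-ratio equivalent of a total copy number
#'
#' Inverse of [ploidyOf()]: `lrr = log2(copies / 2)`.  The conventional
#' high-level amplification cutoff of more than 10 copies corresponds to a
#' log2-ratio of 2.32.
#'
#' @param copies Total copy number (> 0).
#' @return Log2 ratio.
#' @examples
#' lrrForCopies(10)  # 2.32
#' @export
lrrForCopies <- function(copies) {
  stopifnot(all(copies > 0))
  log2(copies / 2)
}

#' Normalize binned read depths for GC content and mappability
#'
#' Bins below the mappability threshold (hard-to-quantify regions) are
#' discarded.  Remaining tumor and normal depths are each divided by a
#' loess-smoothed depth-versus-GC trend and rescaled so the sample median
#' depth is preserved.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`, `gc`,
#'   `mappability`, `depthTumor`, `depthNormal`.
#' @param minMappability Bins with lower mappability are dropped
#'   (default 0.5).
#' @param span Loess span for the GC trend (default 0.5).
#' @return `bins` restricted to mappable rows, with added columns
#'   `normTumor` and `normNormal`.
#' @export
normalizeBins <- function(bins, minMappability = 0.5, span = 0.5) {
  need <- c("chrom", "start", "end", "gc", "mappability",
            "depthTumor", "depthNormal")
  stopifnot(all(need %in% names(bins)))
  keep <- bins$mappability >= minMappability
  if (!any(keep)) stop("all bins fall below the mappability threshold")
  bins <- bins[keep, , drop = FALSE]
  bins$normTumor <- gcCorrect(bins$depthTumor, bins$gc, span)
  bins$normNormal <- gcCorrect(bins$depthNormal, bins$gc, span)
  bins
}

## Divide depth by its smoothed trend against GC, preserving the median.
gcCorrect <- function(depth, gc, span) {
  med <- median(depth)
  if (med <= 0) stop("median depth is not positive")
  if (length(unique(gc)) < 10) {
    ## essentially flat GC: nothing to correct
    return(depth)
  }
  fit <- loess(depth ~ gc, span = span, degree = 2,
               family = "symmetric")
  trend <- predict(fit, newdata = data.frame(gc = gc))
  trend[!is.finite(trend) | trend <= 0] <- med
  corrected <- depth / trend
  corrected * med / median(corrected)
}

#' Per-bin log2 ratios of normalized tumor over normal depth
#'
#' `lrr = log2(normTumor / normNormal)`, centered at zero over putatively
#' neutral regions so the ploidy transform is anchored at the diploid
#' state.  A plain genome-wide median is biased in genomes where a
#' sizeable fraction of bins is gained or lost; instead the genome is cut
#' into half-chromosome blocks, and the zero point is the densest cluster
#' of block mean log-ratios (ties resolved toward the global median).
#' Bins with non-positive normal depth are masked (`NA`).
#'
#' @param bins Output of [normalizeBins()].
#' @param center Recenter at the neutral cluster (default TRUE).
#' @param clusterWidth Width of the block-mean window treated as one
#'   copy-number state (default 0.1 log2 units).
#' @return `bins` with an added `lrr` column.
#' @export
computeLrr <- function(bins, center = TRUE, clusterWidth = 0.1) {
  stopifnot(all(c("normTumor", "normNormal") %in% names(bins)))
  lrr <- rep(NA_real_, nrow(bins))
  ok <- bins$normNormal > 0
  ## a zero-coverage tumor bin over a covered normal bin is a (homozygous)
  ## deletion signal, not missing data: floor the tumor depth at half a read
  lrr[ok] <- log2(pmax(bins$normTumor[ok], 0.5) / bins$normNormal[ok])
  if (center && any(ok)) {
    lrr <- lrr - neutralCenter(lrr[ok], bins$chrom[ok], clusterWidth)
  }
  bins$lrr <- lrr
  bins
}

## Zero point of an LRR profile: mean of the modal cluster of
## half-chromosome block means.
neutralCenter <- function(lrr, chrom, clusterWidth = 0.1) {
  blocks <- unlist(lapply(unique(chrom), function(ch) {
    x <- lrr[chrom == ch]
    if (length(x) < 10L) return(mean(x))
    half <- length(x) %/% 2L
    c(mean(x[seq_len(half)]), mean(x[(half + 1L):length(x)]))
  }), use.names = FALSE)
  blocks <- blocks[is.finite(blocks)]
  if (!length(blocks)) return(0)
  b <- sort(blocks)
  counts <- vapply(seq_along(b), function(i)
    sum(b >= b[i] & b <= b[i] + clusterWidth), integer(1))
  best <- which(counts == max(counts))
  med <- median(lrr)
  centers <- vapply(best, function(i) {
    mean(b[b >= b[i] & b <= b[i] + clusterWidth])
  }, numeric(1))
  centers[which.min(abs(centers - med))]
}

#' Call focal high-level amplifications from a segmented profile
#'
#' Segments with log2-ratio strictly above `lrrCutoff` (default 2.32, i.e.
#' more than 10 total copies) are flagged; contiguous flagged segments are
#' merged.  Amplicons on one chromosome whose log2-ratios agree within
#' `coAmpTol` are grouped as a co-amplification.  Overlapping genes from
#' the genome model are attached.
#'
#' @param segments GRanges from [segmentProfile()].
#' @param genomeModel Genome model list (for gene annotation); optional.
#' @param lrrCutoff Strict lower bound on segment log2-ratio (default 2.32).
#' @param coAmpTol Log2-ratio tolerance for grouping co-amplified loci on
#'   one chromosome (default 0.25).
#' @return data.frame of amplifications: chrom, start, end, lrr, ploidy,
#'   genes (comma-separated), coAmpGroup.
#' @export
callHighLevelAmplifications <- function(segments, genomeModel = NULL,
                                        lrrCutoff = 2.32, coAmpTol = 0.25) {
  stopifnot(is(segments, "GRanges"))
  flag <- S4Vectors::mcols(segments)$lrr > lrrCutoff
  amp <- segments[flag]
  if (!length(amp)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), lrr = numeric(), ploidy = numeric(),
                      genes = character(), coAmpGroup = integer()))
  }
  merged <- GenomicRanges::reduce(amp, with.revmap = TRUE)
  lrrs <- vapply(S4Vectors::mcols(merged)$revmap, function(idx) {
    w <- GenomicRanges::width(amp[idx])
    sum(S4Vectors::mcols(amp[idx])$lrr * w) / sum(w)
  }, numeric(1))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    lrr = lrrs,
    ploidy = ploidyOf(lrrs),
    stringsAsFactors = FALSE
  )
  df$genes <- ""
  if (!is.null(genomeModel)) {
    gr <- geneRanges(genomeModel)
    hits <- GenomicRanges::findOverlaps(merged, gr)
    if (length(hits)) {
      byAmp <- split(S4Vectors::mcols(gr)$gene[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
      for (i in names(byAmp))
        df$genes[as.integer(i)] <- paste(sort(unique(byAmp[[i]])),
                                         collapse = ",")
    }
  }
  ## co-amplification: same chromosome, log2-ratios within tolerance
  df$coAmpGroup <- seq_len(nrow(df))
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    if (length(idx) > 1L) {
      o <- idx[order(df$lrr[idx])]
      grp <- cumsum(c(1, diff(df$lrr[o]) > coAmpTol))
      df$coAmpGroup[o] <- paste0(ch, "_", grp)
    } else {
      df$coAmpGroup[idx] <- paste0(ch, "_1")
    }
  }
  df
}

#' Arm-level copy-number calls from segment mean ploidy
#'
#' For each chromosome arm the length-weighted mean of overlapping segment
#' ploidies is computed; arms with mean ploidy above `gainCutoff` are
#' called gains, below `lossCutoff` losses, otherwise unaltered.  Arms
#' without any covered segment get status `NA`.
#'
#' @param segments GRanges from [segmentProfile()].
#' @param arms Arm definition data.frame (chrom, arm, start, end), e.g.
#'   [armTable()] of the genome model.
#' @param gainCutoff Mean ploidy strictly above this is a gain
#'   (default 2.3).
#' @param lossCutoff Mean ploidy strictly below this is a loss
#'   (default 1.7).
#' @return data.frame: arm, chrom, meanPloidy, status in
#'   \{"gain", "loss", "none", NA\}.
#' @export
callArmEvents <- function(segments, arms, gainCutoff = 2.3,
                          lossCutoff = 1.7) {
  stopifnot(is(segments, "GRanges"),
            all(c("chrom", "arm", "start", "end") %in% names(arms)))
  segDf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(segments)),
    start = GenomicRanges::start(segments),
    end = GenomicRanges::end(segments),
    ploidy = S4Vectors::mcols(segments)$ploidy,
    stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    s <- segDf[segDf$chrom == a$chrom, , drop = FALSE]
    w <- overlapWidth(s$start, s$end, a$start, a$end)
    keep <- w > 0
    if (!any(keep)) {
      return(data.frame(arm = a$arm, chrom = a$chrom,
                        meanPloidy = NA_real_, status = NA_character_,
                        stringsAsFactors = FALSE))
    }
    mp <- sum(s$ploidy[keep] * w[keep]) / sum(w[keep])
    status <- if (mp > gainCutoff) "gain" else if (mp < lossCutoff) "loss"
              else "none"
    data.frame(arm = a$arm, chrom = a$chrom, meanPloidy = mp,
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Detect chromothripsis-like oscillating copy-number patterns
#'
#' A chromosome is flagged when it carries at least `minSegments`
#' copy-number segments whose discretised states (ploidy rounded to the
#' nearest integer) include two or more distinct values, with at least
#' `minSwitches` state switches between adjacent segments — the clustered,
#' oscillating pattern characteristic of a single shattering event.  When
#' a locus of interest is supplied, the call reports whether it lies in a
#' non-diploid segment.
#'
#' @param segments GRanges from [segmentProfile()] for one tumor.
#' @param minSegments Minimum segments on the chromosome (default 8).
#' @param minSwitches Minimum adjacent state switches (default 6).
#' @param locus Optional GRanges of one locus (e.g. RB1) to intersect with
#'   altered segments.
#' @return data.frame per chromosome: chrom, nSegments, nSwitches,
#'   nStates, chromothripsis (logical), locusAltered (logical or NA).
#' @export
detectChromothripsis <- function(segments, minSegments = 8L,
                                 minSwitches = 6L, locus = NULL) {
  stopifnot(is(segments, "GRanges"))
  chroms <- unique(as.character(GenomicRanges::seqnames(segments)))
  res <- lapply(chroms, function(ch) {
    s <- segments[GenomicRanges::seqnames(segments) == ch]
    s <- s[order(GenomicRanges::start(s))]
    state <- pmax(0L, as.integer(round(S4Vectors::mcols(s)$ploidy)))
    switches <- if (length(state) > 1L) sum(diff(state) != 0L) else 0L
    call <- length(s) >= minSegments &&
      length(unique(state)) >= 2L && switches >= minSwitches
    locusAltered <- NA
    if (!is.null(locus) &&
        as.character(GenomicRanges::seqnames(locus))[1] == ch) {
      hit <- GenomicRanges::findOverlaps(locus, s)
      locusAltered <- length(hit) > 0 &&
        any(state[S4Vectors::subjectHits(hit)] != 2L)
    }
    data.frame(chrom = ch, nSegments = length(s), nSwitches = switches,
               nStates = length(unique(state)),
               chromothripsis = call, locusAltered = locusAltered,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cohort-level per-gene recurrence score of copy-number change
#'
#' For each gene, the log2-ratio of the overlapping segment (length-weighted
#' mean when a gene spans a breakpoint) is summed over tumors, separately
#' for gains (positive log2-ratios) and losses (negative), mirroring a
#' cumulative copy-number karyogram.
#'
#' @param segmentsByTumor Named list of per-tumor segment GRanges.
#' @param genes GRanges of gene intervals with a `gene` metadata column.
#' @return data.frame: gene, gainScore (sum of positive contributions),
#'   lossScore (sum of negative contributions, non-positive), score (their
#'   sum).  Genes with no covered segment in any tumor get NA scores.
#' @export
geneRecurrenceScore <- function(segmentsByTumor, genes) {
  stopifnot(is.list(segmentsByTumor), is(genes, "GRanges"))
  nm <- S4Vectors::mcols(genes)$gene
  gain <- loss <- rep(0, length(genes))
  covered <- rep(FALSE, length(genes))
  for (seg in segmentsByTumor) {
    hits <- GenomicRanges::findOverlaps(genes, seg)
    if (!length(hits)) next
    ov <- GenomicRanges::pintersect(
      genes[S4Vectors::queryHits(hits)], seg[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    lrr <- S4Vectors::mcols(seg)$lrr[S4Vectors::subjectHits(hits)]
    num <- tapply(w * lrr, S4Vectors::queryHits(hits), sum)
    den <- tapply(w, S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(num))
    glrr <- as.numeric(num / den)
    covered[idx] <- TRUE
    gain[idx] <- gain[idx] + pmax(glrr, 0)
    loss[idx] <- loss[idx] + pmin(glrr, 0)
  }
  data.frame(gene = nm,
             gainScore = ifelse(covered, gain, NA_real_),
             lossScore = ifelse(covered, loss, NA_real_),
             score = ifelse(covered, gain + loss, NA_real_),
             stringsAsFactors = FALSE)
}

#' Total genomic disturbance as a segment count
#'
#' The number of contiguous equal-copy-number DNA segments in a genome,
#' plus its log10 transform.  An unaltered genome contributes one segment
#' per chromosome (24 for a complete human karyotype, log10 = 0.38); every
#' acquired breakpoint adds segments.
#'
#' @param segments GRanges of one tumor's full-genome segmentation.
#' @return list with `count` and `log10Count`.
#' @export
segmentCountBurden <- function(segments) {
  stopifnot(is(segments, "GRanges"))
  n <- length(segments)
  list(count = n, log10Count = log10(n))
}

#' Estimate genetic sex from chromosome read counts
#'
#' Classifies a sample as male when its fraction of reads mapped to
#' chromosome Y exceeds the midpoint between the expected male and female
#' Y fractions.  When a recorded sex is supplied, a mismatch raises a QC
#' flag: the sample identity is questionable and it should be excluded
#' from downstream analyses.
#'
#' @param readCounts Named numeric vector of mapped read counts per
#'   chromosome; must contain `chrY`.
#' @param recordedSex Optional "male"/"female" from patient records.
#' @param maleYFraction Expected Y read fraction in males (default 0.002).
#' @param femaleYFraction Expected Y read fraction in females
#'   (default 1e-4).
#' @return list: `estimatedSex`, `yFraction`, `qcFlag` (TRUE when the
#'   estimate contradicts the recorded sex).
#' @export
estimateSex <- function(readCounts, recordedSex = NULL,
                        maleYFraction = 0.002, femaleYFraction = 1e-4) {
  stopifnot("chrY" %in% names(readCounts))
  total <- sum(readCounts)
  if (total <= 0) stop("total read count is zero")
  yFrac <- readCounts[["chrY"]] / total
  midpoint <- (maleYFraction + femaleYFraction) / 2
  est <- if (yFrac > midpoint) "male" else "female"
  qc <- !is.null(recordedSex) && !identical(est, recordedSex)
  list(estimatedSex = est, yFraction = yFrac, qcFlag = qc)
}

#' Export segments in SEG format for genome-browser inspection
#'
#' Writes the tab-delimited SEG layout (sample, chrom, start, end,
#' num.mark, seg.mean) accepted by the Integrative Genomics Viewer.
#'
#' @param segmentsByTumor Named list of per-tumor segment GRanges.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
writeSeg <- function(segmentsByTumor, file) {
  rows <- lapply(names(segmentsByTumor), function(id) {
    s <- segmentsByTumor[[id]]
    data.frame(
      sample = id,
      chrom = as.character(GenomicRanges::seqnames(s)),
      start = GenomicRanges::start(s),
      end = GenomicRanges::end(s),
      num.mark = S4Vectors::mcols(s)$nBins,
      seg.mean = round(S4Vectors::mcols(s)$lrr, 4),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  names(df) <- c("ID", "chrom", "loc.start", "loc.end", "num.mark",
                 "seg.mean")
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
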