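## Mirrored-BAF allelic imbalance and LOH calling.
##
## Marker tables are data.frames with one row per (sample, position):
## columns sample, chrom, pos, depth, baf, genotypeNormal.

#' Cohort-level BAF marker filter
#'
#' Retains variant positions with at least `minDepth` coverage in at least
#' `minSampleFraction` of the samples (both thresholds inclusive).
#'
#' @param markers Marker data.frame (sample, chrom, pos, depth, ...).
#' @param minDepth Minimum depth per sample (default 20).
#' @param minSampleFraction Minimum fraction of samples meeting `minDepth`
#'   (default 0.8).
#' @return `markers` restricted to retained positions.
#' @export
filterMarkers <- function(markers, minDepth = 20, minSampleFraction = 0.8) {
  stopifnot(all(c("sample", "chrom", "pos", "depth") %in% names(markers)))
  key <- paste(markers$chrom, markers$pos, sep = ":")
  nSamples <- length(unique(markers$sample))
  okFrac <- tapply(markers$depth >= minDepth, key, mean)
  presentFrac <- tapply(markers$sample, key, function(s)
    length(unique(s))) / nSamples
  ## a position absent from a sample counts as failing the depth threshold
  covFrac <- okFrac * presentFrac
  keep <- names(covFrac)[covFrac >= minSampleFraction]
  markers[key %in% keep, , drop = FALSE]
}

#' Mirror a B-allele frequency onto \[0.5, 1\]
#'
#' `mbaf = max(baf, 1 - baf)`: folds the BAF about 0.5 so allelic
#' imbalance is one-sided regardless of which parental allele is
#' affected.  Idempotent.
#'
#' @param baf Numeric BAF values in \[0, 1\].
#' @return Mirrored BAF values in \[0.5, 1\].
#' @examples
#' mirrorBaf(c(0.3, 0.5, 0.9))
#' @export
mirrorBaf <- function(baf) {
  assertFraction(baf, "baf")
  pmax(baf, 1 - baf)
}

#' Segment mirrored BAF and call allelic imbalance
#'
#' Markers (restricted to sites heterozygous in the matched normal) are
#' mirrored and segmented per chromosome by recursive binary segmentation;
#' a segment is called `allelic_imbalance` when its mean mBAF strictly
#' exceeds `aiThreshold` and it comprises at least `minMarkers`
#' consecutive markers, otherwise `balanced`.  Chromosomes with fewer
#' than `minMarkers` markers are balanced by default.
#'
#' @param markers One sample's marker data.frame (chrom, pos, baf, and
#'   optionally genotypeNormal to select heterozygous sites).
#' @param aiThreshold Strict lower bound on segment mean mBAF for an
#'   allelic-imbalance call (default 0.6).
#' @param minMarkers Minimum consecutive markers per called segment
#'   (default 5).
#' @param hetRange Normal-BAF window treated as heterozygous when
#'   `genotypeNormal` is absent (default c(0.25, 0.75)).
#' @param alpha,nPerm Segmentation permutation-test parameters.
#' @return data.frame of segments: chrom, start, end, nMarkers, meanMbaf,
#'   status in \{"balanced", "allelic_imbalance"\}.
#' @seealso [callLoh()]
#' @export
segmentMbaf <- function(markers, aiThreshold = 0.6, minMarkers = 5L,
                        hetRange = c(0.25, 0.75), alpha = 0.01,
                        nPerm = 1000L) {
  stopifnot(all(c("chrom", "pos", "baf") %in% names(markers)))
  if ("genotypeNormal" %in% names(markers)) {
    markers <- markers[markers$genotypeNormal == "AB", , drop = FALSE]
  } else if ("bafNormal" %in% names(markers)) {
    markers <- markers[markers$bafNormal >= hetRange[1] &
                         markers$bafNormal <= hetRange[2], , drop = FALSE]
  }
  out <- lapply(unique(markers$chrom), function(ch) {
    m <- markers[markers$chrom == ch, , drop = FALSE]
    m <- m[order(m$pos), , drop = FALSE]
    mb <- mirrorBaf(m$baf)
    if (nrow(m) < minMarkers) {
      return(data.frame(chrom = ch, start = min(m$pos), end = max(m$pos),
                        nMarkers = nrow(m), meanMbaf = mean(mb),
                        status = "balanced", stringsAsFactors = FALSE))
    }
    lens <- segmentSeries(mb, alpha = alpha, minBins = minMarkers,
                          nPerm = nPerm)
    endIdx <- cumsum(lens)
    startIdx <- c(1L, head(endIdx, -1L) + 1L)
    means <- vapply(seq_along(lens), function(i)
      mean(mb[startIdx[i]:endIdx[i]]), numeric(1))
    data.frame(
      chrom = ch,
      start = m$pos[startIdx],
      end = m$pos[endIdx],
      nMarkers = as.integer(lens),
      meanMbaf = means,
      status = ifelse(means > aiThreshold & lens >= minMarkers,
                      "allelic_imbalance", "balanced"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Upgrade allelic imbalance to loss of heterozygosity
#'
#' Allelic-imbalance segments whose mean mBAF strictly exceeds
#' `lohThreshold` are upgraded to `loh`; a segment at exactly the
#' threshold stays `allelic_imbalance`.
#'
#' @param segments Output of [segmentMbaf()].
#' @param lohThreshold Strict lower bound on segment mean mBAF for LOH
#'   (default 0.8).
#' @return `segments` with the `status` column upgraded where applicable.
#' @export
callLoh <- function(segments, lohThreshold = 0.8) {
  stopifnot(all(c("meanMbaf", "status") %in% names(segments)))
  up <- segments$status == "allelic_imbalance" &
    segments$meanMbaf > lohThreshold
  segments$status[up] <- "loh"
  segments
}

#' Status of a locus in a sample's mBAF segmentation
#'
#' Convenience lookup: the status of the segment overlapping a position
#' (balanced when no segment covers it).
#'
#' @param segments Output of [segmentMbaf()]/[callLoh()].
#' @param chrom,pos Locus to query.
#' @return One of "balanced", "allelic_imbalance", "loh".
#' @export
lohStatusAt <- function(segments, chrom, pos) {
  hit <- segments$chrom == chrom & segments$start <= pos &
    segments$end >= pos
  if (!any(hit)) return("balanced")
  st <- segments$status[hit]
  if ("loh" %in% st) "loh"
  else if ("allelic_imbalance" %in% st) "allelic_imbalance"
  else "balanced"
}
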