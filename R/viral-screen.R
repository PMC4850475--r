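## K-mer seed-and-extend read classifier for viral presence/absence
## counting.  The scientific quantity of interest is a per-virus count of
## well-matched reads (with a spike-in phage as positive control), so a
## seed-vote classifier with an ungapped extension check is used rather
## than a full aligner.

#' Build a k-mer index over a set of viral reference genomes
#'
#' Indexes every k-mer position of every reference (forward strand).
#' Reference names must be unique.
#'
#' @param references Named character vector or
#'   [Biostrings::DNAStringSet] of reference sequences.
#' @param k K-mer length (default 21).
#' @return A list with the index table, the sequences and `k`.
#' @export
buildViralIndex <- function(references, k = 21L) {
  if (is(references, "DNAStringSet"))
    references <- setNames(as.character(references), names(references))
  stopifnot(length(references) >= 1L, !is.null(names(references)),
            !anyDuplicated(names(references)))
  if (any(nchar(references) < k))
    stop("every reference must be at least k bases long")
  tabs <- lapply(names(references), function(nm) {
    s <- references[[nm]]
    n <- nchar(s) - k + 1L
    data.table::data.table(
      kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
      virus = nm,
      refPos = seq_len(n)
    )
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  list(index = idx, sequences = references, k = as.integer(k))
}

## Count mismatches between two equal-length strings.
countMismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## Seed votes of one read against an index: virus -> (votes, best diagonal)
seedVotes <- function(read, idx) {
  k <- idx$k
  n <- nchar(read) - k + 1L
  if (n < 1L) return(NULL)
  q <- data.table::data.table(
    kmer = substring(read, seq_len(n), seq_len(n) + k - 1L),
    readPos = seq_len(n)
  )
  hits <- idx$index[q, on = "kmer", nomatch = NULL]
  if (!nrow(hits)) return(NULL)
  hits[, diag := refPos - readPos]
  ## votes on the best diagonal per virus (collinear seeds)
  ag <- hits[, .N, by = .(virus, diag)]
  ag[ag[, .I[which.max(N)], by = virus]$V1]
}

## Ungapped extension: mismatch fraction of the read aligned at a diagonal.
extensionMismatchFraction <- function(read, refSeq, diag) {
  readLen <- nchar(read)
  refStart <- diag + 1L
  refEnd <- diag + readLen
  clipStart <- max(1L, refStart)
  clipEnd <- min(nchar(refSeq), refEnd)
  if (clipEnd < clipStart) return(1)
  rdStart <- clipStart - diag
  rdEnd <- clipEnd - diag
  overlap <- clipEnd - clipStart + 1L
  if (overlap < readLen / 2) return(1)   # hanging off the reference
  mm <- countMismatches(substring(read, rdStart, rdEnd),
                        substring(refSeq, clipStart, clipEnd))
  mm / overlap
}

#' Classify reads against viral references by k-mer seed votes
#'
#' Each read (checked on both strands) is assigned to the virus sharing
#' the most collinear seed k-mers, provided the vote count reaches
#' `minSeedHits` and an ungapped extension at the implied offset has a
#' mismatch fraction of at most `maxMismatchFraction`.  Ties between
#' viruses leave the read unassigned.  When a host decoy is supplied,
#' reads with seed support on the decoy are removed before viral
#' assignment.  Assignment is deterministic and independent of read
#' order.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of reads.
#' @param index Viral index from [buildViralIndex()].
#' @param hostIndex Optional host-decoy index from [buildViralIndex()].
#' @param minSeedHits Minimum collinear seed votes (default 2).
#' @param maxMismatchFraction Maximum mismatch fraction of the extension
#'   (default 0.1).
#' @return A list: `hits` (data.frame virus, reads, fractionOfViral),
#'   `totalReads`, `assigned`, `hostFiltered`.
#' @export
classifyReads <- function(reads, index, hostIndex = NULL, minSeedHits = 2L,
                          maxMismatchFraction = 0.1) {
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  stopifnot(length(index$sequences) >= 1L)
  if (any(nchar(reads) < index$k))
    stop("reads shorter than k cannot be classified")
  total <- length(reads)
  assignVirus <- function(read) {
    best <- NULL
    for (r in c(read, revComp(read))) {
      v <- seedVotes(r, index)
      if (is.null(v)) next
      v <- v[N >= minSeedHits]
      if (!nrow(v)) next
      top <- v[N == max(N)]
      if (nrow(top) > 1L) next            # ambiguous: unassigned
      frac <- extensionMismatchFraction(
        r, index$sequences[[top$virus]], top$diag)
      if (frac <= maxMismatchFraction &&
          (is.null(best) || top$N > best$N))
        best <- list(virus = top$virus, N = top$N)
    }
    if (is.null(best)) NA_character_ else best$virus
  }
  hostFiltered <- 0L
  if (!is.null(hostIndex)) {
    isHost <- vapply(reads, function(read) {
      any(vapply(c(read, revComp(read)), function(r) {
        v <- seedVotes(r, hostIndex)
        !is.null(v) && any(v$N >= minSeedHits)
      }, logical(1)))
    }, logical(1), USE.NAMES = FALSE)
    hostFiltered <- sum(isHost)
    reads <- reads[!isHost]
  }
  assigned <- vapply(reads, assignVirus, character(1), USE.NAMES = FALSE)
  counts <- table(assigned[!is.na(assigned)])
  hits <- data.frame(
    virus = as.character(names(counts)),
    reads = as.integer(counts),
    fractionOfViral = numeric(length(counts)),
    stringsAsFactors = FALSE
  )
  if (nrow(hits)) {
    hits <- hits[order(-hits$reads, hits$virus), , drop = FALSE]
    hits$fractionOfViral <- hits$reads / sum(hits$reads)
  }
  rownames(hits) <- NULL
  list(hits = hits, totalReads = total,
       assigned = sum(!is.na(assigned)), hostFiltered = hostFiltered)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
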