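## Synthetic viral references and spike-in read sets for the viral
## screening module.  All sequences are synthetic stand-ins generated from
## a seeded RNG; the phiX-like genome mimics the length of the phage
## spiked into sequencing libraries as a positive control.

randomDna <- function(n, gc = 0.45) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Synthetic viral reference set with a host decoy
#'
#' Builds a named set of synthetic genomes: a phiX-like spike-in control
#' (5386 bp), a configurable number of other viral genomes, and a longer
#' host decoy sequence used for host-read subtraction.
#'
#' @param nOtherViruses Number of non-spike viral genomes (default 3).
#' @param seed Integer seed.
#' @return list: `viral` (named character vector, first element
#'   "phiX_like"), `host` (single unnamed character string).
#' @export
makeViralReferences <- function(nOtherViruses = 3L, seed = 1L) {
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(seed)
  viral <- c(phiX_like = randomDna(5386L))
  if (nOtherViruses > 0L) {
    others <- vapply(seq_len(nOtherViruses),
                     function(i) randomDna(sample(5000:9000, 1)),
                     character(1))
    names(others) <- sprintf("virus_%02d", seq_len(nOtherViruses))
    viral <- c(viral, others)
  }
  list(viral = viral, host = randomDna(30000L, gc = 0.41))
}

#' Sample sequencing reads from viral genomes and a host background
#'
#' Draws `spikeCounts[v]` reads uniformly from each named viral genome and
#' `hostReads` reads from the host sequence, applies uniform substitution
#' errors at `errorRate`, and records the per-virus truth counts.
#'
#' @param references Output of [makeViralReferences()] (or a compatible
#'   list with `viral` and `host`).
#' @param spikeCounts Named integer vector: reads per viral genome
#'   (names must exist in `references$viral`); counts must be >= 0.
#' @param readLength Read length in bp (default 100); must not exceed the
#'   shortest sampled reference.
#' @param errorRate Per-base substitution error rate (default 0.001).
#' @param hostReads Number of host background reads (default 0).
#' @param seed Integer seed.
#' @return list: `reads` (character vector, names encode the source),
#'   `truth` (data.frame virus, reads — viruses with zero requested reads
#'   are omitted).
#' @export
generateViralReads <- function(references, spikeCounts, readLength = 100L,
                               errorRate = 0.001, hostReads = 0L,
                               seed = 1L) {
  stopifnot(all(spikeCounts >= 0), !is.null(names(spikeCounts)),
            all(names(spikeCounts) %in% names(references$viral)))
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(seed)
  sampleFrom <- function(seqStr, count, label) {
    if (count == 0L) return(character(0))
    if (readLength > nchar(seqStr))
      stop("readLength exceeds the length of reference '", label, "'")
    starts <- sample(nchar(seqStr) - readLength + 1L, count,
                     replace = TRUE)
    reads <- substring(seqStr, starts, starts + readLength - 1L)
    reads <- vapply(reads, addErrors, character(1),
                    errorRate = errorRate, USE.NAMES = FALSE)
    names(reads) <- sprintf("%s_read%06d", label, seq_len(count))
    reads
  }
  reads <- character(0)
  for (v in names(spikeCounts))
    reads <- c(reads, sampleFrom(references$viral[[v]], spikeCounts[[v]], v))
  if (hostReads > 0L)
    reads <- c(reads, sampleFrom(references$host, hostReads, "host"))
  truth <- data.frame(virus = names(spikeCounts),
                      reads = as.integer(spikeCounts),
                      stringsAsFactors = FALSE)
  truth <- truth[truth$reads > 0L, , drop = FALSE]
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

addErrors <- function(read, errorRate) {
  if (errorRate <= 0) return(read)
  n <- nchar(read)
  hit <- which(runif(n) < errorRate)
  if (!length(hit)) return(read)
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Write reads as FASTQ / read a FASTQ into a character vector
#'
#' Minimal plain-text FASTQ emission for simulated reads (constant base
#' quality), and reading through Biostrings.
#'
#' @param reads Named character vector of reads.
#' @param file Path.
#' @return The path invisibly / a named character vector of reads.
#' @export
writeFastq <- function(reads, file) {
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname writeFastq
#' @export
readFastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write reference sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param file Path.
#' @return The path invisibly.
#' @export
writeFasta <- function(seqs, file) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), file)
  invisible(file)
}
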