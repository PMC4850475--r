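#' @import methods
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' CohortSpec: parameters of a synthetic tumor/normal cohort
#'
#' Describes the study conditions a simulated cohort should emulate:
#' cohort size, the purity range the tumors are drawn from, sequencing
#' depth, the copy-number bin width, and the reduced genome model.
#' All randomness downstream derives from the single `seed` slot, so a
#' fixed spec yields byte-identical simulated data.
#'
#' @slot nTumors Number of tumor/normal pairs.
#' @slot purityRange Length-2 numeric in \[0, 1\]: tumors draw their purity
#'   (tumor-cell fraction) uniformly from this interval.
#' @slot meanDepth Expected read depth at variant sites and per
#'   copy-number bin in the diploid state.
#' @slot binSize Copy-number bin width in bp (default 20000).
#' @slot genomeModel Reduced genome model list (see [defaultGenomeModel()]).
#' @slot seed Integer seed controlling all simulation randomness.
#' @export
setClass("CohortSpec",
  representation(
    nTumors = "integer",
    purityRange = "numeric",
    meanDepth = "numeric",
    binSize = "integer",
    genomeModel = "list",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nTumors) != 1L || is.na(object@nTumors) ||
      object@nTumors < 1L)
    msg <- c(msg, "nTumors must be a single positive integer")
  if (length(object@purityRange) != 2L ||
      any(object@purityRange < 0) || any(object@purityRange > 1) ||
      object@purityRange[1] > object@purityRange[2])
    msg <- c(msg, "purityRange must be an ordered pair in [0, 1]")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@binSize <= 0L) msg <- c(msg, "binSize must be > 0")
  if (!all(c("arms", "genes", "chromLength") %in% names(object@genomeModel)))
    msg <- c(msg, "genomeModel must have arms, genes and chromLength")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param nTumors Number of tumor/normal pairs.
#' @param purityRange Interval tumors draw purity from, default `c(0.9, 1)`
#'   (retinoblastoma specimens are typically highly pure).
#' @param meanDepth Expected diploid depth (default 100).
#' @param binSize Copy-number bin width in bp (default 20000).
#' @param genomeModel Reduced genome model; default [defaultGenomeModel()].
#' @param seed Integer seed.
#' @return A [CohortSpec-class] object.
#' @examples
#' spec <- CohortSpec(nTumors = 4, seed = 1)
#' spec
#' @export
CohortSpec <- function(nTumors = 24L, purityRange = c(0.9, 1),
                       meanDepth = 100, binSize = 20000L,
                       genomeModel = defaultGenomeModel(), seed = 1L) {
  new("CohortSpec",
      nTumors = as.integer(nTumors),
      purityRange = as.numeric(purityRange),
      meanDepth = as.numeric(meanDepth),
      binSize = as.integer(binSize),
      genomeModel = genomeModel,
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nTumors, "tumor/normal pairs\n")
  cat("  purity ~ U(", object@purityRange[1], ", ", object@purityRange[2],
      "), mean depth ", object@meanDepth, "x\n", sep = "")
  cat("  bins of", object@binSize, "bp over",
      nrow(object@genomeModel$arms) / 2, "chromosomes; seed",
      object@seed, "\n")
})

#' GroundTruth: hidden parameters of a simulated cohort
#'
#' Records everything the simulator decided, so recovery of purity, clonal
#' fractions and implanted events can be scored exactly.
#'
#' @slot tumors data.frame, one row per tumor: id, purity, rb1Mode, sex,
#'   ageMonths, laterality, heredity.
#' @slot events data.frame of implanted copy-number events: tumor, region
#'   (arm name or gene), chrom, start, end, copyChange, clonalFraction.
#' @slot secondaryVariants data.frame: tumor, gene, expectedVAF, consequence.
#' @slot chromothripsis data.frame: tumor, chrom, nSegments, mode.
#' @slot viralSpike data.frame: virus, reads.
#' @export
setClass("GroundTruth",
  representation(
    tumors = "data.frame",
    events = "data.frame",
    secondaryVariants = "data.frame",
    chromothripsis = "data.frame",
    viralSpike = "data.frame"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  tu <- object@tumors
  if (nrow(tu) && (any(tu$purity < 0) || any(tu$purity > 1)))
    msg <- c(msg, "purity must lie in [0, 1]")
  ev <- object@events
  if (nrow(ev) && (any(ev$clonalFraction <= 0) || any(ev$clonalFraction > 1)))
    msg <- c(msg, "clonalFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth for", nrow(object@tumors), "tumors:",
      nrow(object@events), "copy-number events,",
      nrow(object@secondaryVariants), "secondary variants,",
      nrow(object@chromothripsis), "chromothripsis regions\n")
  if (nrow(object@tumors))
    print(table(rb1Mode = object@tumors$rb1Mode))
})

#' @describeIn GroundTruth-class per-tumor truth table accessor
#' @param x A GroundTruth object.
#' @export
truthTumors <- function(x) { stopifnot(is(x, "GroundTruth")); x@tumors }

#' @describeIn GroundTruth-class implanted copy-number event accessor
#' @export
truthEvents <- function(x) { stopifnot(is(x, "GroundTruth")); x@events }

#' GermlineDB: pooled, anonymized germline variant database
#'
#' The union of variant keys (chrom, pos, ref, alt, genotype class) over
#' all sequenced normals.  Per-patient attribution is discarded at
#' construction: only the pooled key set is retained, and lookups are
#' order-independent.
#'
#' @slot keys Character vector of unique variant keys.
#' @export
setClass("GermlineDB", representation(keys = "character"))

setMethod("show", "GermlineDB", function(object) {
  cat("GermlineDB with", length(object@keys), "pooled variant keys\n")
})

#' @describeIn GermlineDB-class number of pooled keys
#' @param x A GermlineDB.
#' @export
setMethod("length", "GermlineDB", function(x) length(x@keys))

#' EventMatrix: tumors-by-events binary somatic event matrix
#'
#' Rows are events (gene SNV/INDEL, focal loss/amplification, arm-level
#' gain/loss, chromothripsis, LOH at a locus), columns are tumor samples.
#' Entries are 1 (event occurred), 0 (did not occur) or NA (data not
#' available for that tumor and event).
#'
#' @slot matrix Integer matrix with dimnames; values 0/1/NA.
#' @export
setClass("EventMatrix", representation(matrix = "matrix"))

setValidity("EventMatrix", function(object) {
  m <- object@matrix
  msg <- character()
  if (!all(m[!is.na(m)] %in% c(0L, 1L)))
    msg <- c(msg, "entries must be 0, 1 or NA")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "event (row) and tumor (column) names are required")
  if (length(msg)) msg else TRUE
})

#' Construct an EventMatrix from a 0/1/NA matrix
#'
#' @param m Matrix (rows = events, columns = tumors) with dimnames.
#' @return An [EventMatrix-class].
#' @export
EventMatrix <- function(m) {
  storage.mode(m) <- "integer"
  new("EventMatrix", matrix = m)
}

setMethod("show", "EventMatrix", function(object) {
  m <- object@matrix
  cat("EventMatrix:", nrow(m), "events x", ncol(m), "tumors (",
      sum(is.na(m)), "missing entries )\n")
  freq <- rowMeans(m == 1L, na.rm = TRUE)
  for (i in seq_len(min(nrow(m), 12)))
    cat(sprintf("  %-22s %5.1f%%\n", rownames(m)[i], 100 * freq[i]))
  if (nrow(m) > 12) cat("  ...\n")
})

#' @describeIn EventMatrix-class the underlying integer matrix
#' @param x An EventMatrix.
#' @export
eventMatrix <- function(x) { stopifnot(is(x, "EventMatrix")); x@matrix }

#' @describeIn EventMatrix-class event (row) names
#' @export
eventNames <- function(x) rownames(eventMatrix(x))

#' @describeIn EventMatrix-class tumor (column) identifiers
#' @export
tumorIds <- function(x) colnames(eventMatrix(x))

#' @describeIn EventMatrix-class dimensions (events, tumors)
#' @export
setMethod("dim", "EventMatrix", function(x) dim(x@matrix))
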