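#' Reduced genome model for simulation and testing
#'
#' The simulator and the cohort pipeline operate on a reduced genome: a
#' handful of mini-chromosomes, each split into a p and a q arm, carrying
#' the loci that matter for retinoblastoma biology (RB1 on 13q, MYCN on 2p,
#' BCOR on Xp, CREBBP on 16p) plus the arms recurrently altered in this
#' tumor type (1q, 2p, 6p, 16q).  Coordinates are arbitrary but internally
#' consistent, 1-based inclusive; real hg19 sizes are deliberately not used
#' so that full-cohort simulations run in seconds.
#'
#' @param chromLength Length in bp of each mini-chromosome.
#' @return A list with elements `arms` (data.frame: chrom, arm, start, end),
#'   `genes` (data.frame: gene, chrom, start, end) and `chromLength`.
#' @examples
#' gm <- defaultGenomeModel()
#' subset(gm$genes, gene == "RB1")
#' @export
defaultGenomeModel <- function(chromLength = 4e6) {
  stopifnot(chromLength >= 1e6)
  chroms <- c("chr1", "chr2", "chr6", "chr13", "chr16", "chrX")
  half <- floor(chromLength / 2)
  arms <- do.call(rbind, lapply(chroms, function(ch) {
    nm <- sub("chr", "", ch)
    data.frame(
      chrom = ch,
      arm = paste0(nm, c("p", "q")),
      start = c(1L, half + 1L),
      end = c(half, as.integer(chromLength)),
      stringsAsFactors = FALSE
    )
  }))
  ## loci placed mid-arm so focal events never straddle an arm boundary
  genes <- data.frame(
    gene  = c("RB1",       "MYCN",    "BCOR",   "CREBBP", "MDM4",   "CDH11"),
    chrom = c("chr13",     "chr2",    "chrX",   "chr16",  "chr1",   "chr16"),
    start = c(half + 4e5,  8e5,       5e5,      4e5,      half + 1e6, half + 1e6),
    end   = c(half + 5.8e5, 8.6e5,    5.6e5,    5.6e5,    half + 1.04e6, half + 1.1e6),
    stringsAsFactors = FALSE
  )
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  list(arms = arms, genes = genes, chromLength = as.integer(chromLength))
}

#' Convert the gene table of a genome model to GRanges
#'
#' @param genomeModel A genome model list as returned by
#'   [defaultGenomeModel()].
#' @return A [GenomicRanges::GRanges] with a `gene` metadata column.
#' @export
geneRanges <- function(genomeModel) {
  g <- genomeModel$genes
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                         gene = g$gene)
}

#' Arm definitions of a genome model as a data.frame
#'
#' @inheritParams geneRanges
#' @return data.frame with columns chrom, arm, start, end.
#' @export
armTable <- function(genomeModel) genomeModel$arms
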