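## Cohort-level orchestration: run every stage on a (simulated or loaded)
## cohort, classify the primary driver per tumor, and assemble the cohort
## report.

#' Classify the primary disease-causing event of one tumor
#'
#' Precedence: biallelic RB1 small variants (two hits, or one hit plus
#' LOH / copy loss at the RB1 locus) classify the tumor as RB1-driven;
#' otherwise homozygous copy-number loss of RB1; otherwise high-level
#' focal MYCN amplification; otherwise undetermined.  Co-occurring MYCN
#' amplification is reported alongside an RB1 classification, never
#' suppressed.  LOH at RB1 without a detected small variant is strong
#' indirect evidence of RB1 inactivation; by default it vetoes a
#' MYCN-primary classification (the variant itself may simply have been
#' missed by sequencing), which is configurable.
#'
#' @param rb1Snvs Number of somatic pathogenic RB1 SNV/INDELs detected.
#' @param rb1Loh Logical: LOH or allelic imbalance at the RB1 locus.
#' @param rb1Ploidy Mean ploidy of the RB1 locus (NA when unavailable).
#' @param mycnAmplified Logical: focal high-level MYCN amplification.
#' @param lossPloidy RB1 ploidy below this counts as copy loss supporting
#'   a second hit (default 1.5); below `homLossPloidy` (default 0.75) as
#'   homozygous loss.
#' @param homLossPloidy See `lossPloidy`.
#' @param lohVetoesMycn When TRUE (default), RB1 LOH blocks a
#'   MYCN-primary call.
#' @return list: `class` in \{"RB1_biallelic", "RB1_loss", "MYCN_amp",
#'   "undetermined"\}, `mycnCoAmplified`, `evidence`.
#' @export
classifyDriver <- function(rb1Snvs, rb1Loh, rb1Ploidy, mycnAmplified,
                           lossPloidy = 1.5, homLossPloidy = 0.75,
                           lohVetoesMycn = TRUE) {
  rb1CopyLoss <- !is.na(rb1Ploidy) && rb1Ploidy < lossPloidy
  rb1HomLoss <- !is.na(rb1Ploidy) && rb1Ploidy < homLossPloidy
  cls <- if (rb1Snvs >= 2L || (rb1Snvs == 1L && (rb1Loh || rb1CopyLoss))) {
    "RB1_biallelic"
  } else if (rb1HomLoss) {
    "RB1_loss"
  } else if (mycnAmplified && !(lohVetoesMycn && rb1Loh)) {
    "MYCN_amp"
  } else {
    "undetermined"
  }
  list(class = cls,
       mycnCoAmplified = mycnAmplified && cls != "MYCN_amp",
       evidence = list(rb1Snvs = rb1Snvs, rb1Loh = rb1Loh,
                       rb1Ploidy = rb1Ploidy,
                       mycnAmplified = mycnAmplified))
}

#' Mean ploidy of a region from bin-level log2 ratios
#'
#' `2 * 2^mean(lrr)` over the bins covering the region: the amplitude
#' measurement used when converting an arm-level loss into a subclonal
#' fraction, independent of segmentation breakpoints.
#'
#' @param bins Bin data.frame with an `lrr` column (see [computeLrr()]).
#' @param chrom,start,end Region (1-based inclusive).
#' @return Mean ploidy, or NA when no bin covers the region.
#' @export
regionPloidyFromBins <- function(bins, chrom, start, end) {
  hit <- bins$chrom == chrom &
    overlapWidth(bins$start, bins$end, start, end) > 0 &
    is.finite(bins$lrr)
  if (!any(hit)) return(NA_real_)
  ploidyOf(mean(bins$lrr[hit]))
}

armPloidyAt <- function(armCalls, armName) {
  i <- match(armName, armCalls$arm)
  if (is.na(i)) NA_real_ else armCalls$meanPloidy[i]
}

segmentPloidyAt <- function(segments, chrom, start, end) {
  hit <- as.character(GenomicRanges::seqnames(segments)) == chrom &
    overlapWidth(GenomicRanges::start(segments),
                 GenomicRanges::end(segments), start, end) > 0
  if (!any(hit)) return(NA_real_)
  s <- segments[hit]
  w <- overlapWidth(GenomicRanges::start(s), GenomicRanges::end(s),
                    start, end)
  sum(S4Vectors::mcols(s)$ploidy * w) / sum(w)
}

#' Run the full somatic-landscape pipeline on a cohort
#'
#' Executes every stage on an in-memory cohort (typically from
#' [simulateCohort()]): sex QC (mismatched samples are excluded and
#' flagged), pooled-germline somatic variant calling with pathogenicity
#' filtering and recurrence, copy-number normalization / segmentation /
#' arm and amplification and chromothripsis calls, mBAF LOH calling,
#' purity and subclonal-fraction estimation, driver classification with
#' sensitivity bookkeeping against the ground truth, and the binary
#' event matrix with mutual-exclusivity and phenotype-association
#' statistics.
#'
#' @param cohort Cohort list from [simulateCohort()].
#' @param alpha,nPerm Segmentation parameters (defaults 0.01 / 1000).
#' @param viral Optional list with elements `reads` (character vector or
#'   DNAStringSet), `index` (from [buildViralIndex()]) and optionally
#'   `hostIndex`; when given, reads are classified and the per-virus hit
#'   table is included in the report.
#' @param outputDir Optional directory: when given, SEG, event-matrix and
#'   report JSON artifacts are written there.
#' @param verbose Log per-stage progress and record counts.
#' @return A CohortReport list: `qc`, `funnel`, `recurrent`, `purity`,
#'   `clonality`, `armCalls`, `amplifications`, `chromothripsis`, `loh`,
#'   `drivers`, `sensitivity`, `eventMatrix`, `exclusivity`,
#'   `phenotypeAssociations`, `viral` (NULL unless reads were supplied),
#'   `segments`, `excluded`.
#' @export
runCohort <- function(cohort, alpha = 0.01, nPerm = 1000L,
                      viral = NULL, outputDir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  gm <- cohort$spec@genomeModel
  arms <- armTable(gm)
  genes <- gm$genes
  rb1 <- genes[genes$gene == "RB1", ]
  mycn <- genes[genes$gene == "MYCN", ]
  truth <- cohort$groundTruth

  ## --- sex QC ---------------------------------------------------------
  ids <- names(cohort$variantTables)
  qc <- lapply(ids, function(id) {
    recorded <- cohort$phenotypes$sex[match(id, cohort$phenotypes$patient)]
    estimateSex(cohort$readCounts[[id]], recordedSex = recorded)
  })
  names(qc) <- ids
  excluded <- ids[vapply(qc, `[[`, logical(1), "qcFlag")]
  keep <- setdiff(ids, excluded)
  if (length(excluded))
    say("excluding %s after sex QC", paste(excluded, collapse = ", "))

  ## --- somatic variants ----------------------------------------------
  normals <- lapply(cohort$variantTables[keep], `[[`, "normal")
  db <- buildGermlineDb(normals)
  tumors <- lapply(cohort$variantTables[keep], `[[`, "tumor")
  nTotal <- sum(vapply(tumors, nrow, integer(1)))
  filtered <- lapply(tumors, qualityFilter)
  nQual <- sum(vapply(filtered, nrow, integer(1)))
  somatic <- lapply(filtered, callSomatic, db = db)
  nSomatic <- sum(vapply(somatic, nrow, integer(1)))
  pathogenic <- lapply(somatic, pathogenicityFilter)
  somaticAll <- do.call(rbind, c(somatic, list(make.row.names = FALSE)))
  pathogenicAll <- do.call(rbind, c(pathogenic,
                                    list(make.row.names = FALSE)))
  funnel <- variantFunnel(nTotal, nQual, nSomatic, nrow(pathogenicAll))
  recurrent <- recurrentGenes(pathogenicAll)
  say("variant funnel: %d -> %d -> %d -> %d records", nTotal, nQual,
      nSomatic, nrow(pathogenicAll))

  ## --- copy number ----------------------------------------------------
  segments <- list(); armCalls <- list(); amps <- list(); ct <- list()
  binsByTumor <- list()
  rb1Locus <- GenomicRanges::GRanges(
    rb1$chrom, IRanges::IRanges(rb1$start, rb1$end))
  for (id in keep) {
    bins <- computeLrr(normalizeBins(cohort$binTables[[id]]))
    binsByTumor[[id]] <- bins
    seg <- segmentProfile(bins, alpha = alpha, nPerm = nPerm)
    segments[[id]] <- seg
    ac <- callArmEvents(seg, arms)
    ac$patient <- id
    armCalls[[id]] <- ac
    am <- callHighLevelAmplifications(seg, gm)
    if (nrow(am)) am$patient <- id
    amps[[id]] <- am
    cc <- detectChromothripsis(seg, locus = rb1Locus)
    cc$patient <- id
    ct[[id]] <- cc
  }
  armCallsAll <- do.call(rbind, c(armCalls, list(make.row.names = FALSE)))
  ampsAll <- do.call(rbind, c(amps[vapply(amps, nrow, integer(1)) > 0],
                              list(make.row.names = FALSE)))
  ctAll <- do.call(rbind, c(ct, list(make.row.names = FALSE)))
  say("copy number: %d segments across %d tumors",
      sum(vapply(segments, length, integer(1))), length(keep))

  ## --- LOH ------------------------------------------------------------
  loh <- lapply(keep, function(id) {
    seg <- callLoh(segmentMbaf(cohort$bafTables[[id]], nPerm = nPerm,
                               alpha = alpha))
    seg$patient <- id
    seg
  })
  names(loh) <- keep
  lohAll <- do.call(rbind, c(loh, list(make.row.names = FALSE)))
  rb1LohByTumor <- vapply(keep, function(id) {
    lohStatusAt(loh[[id]], rb1$chrom, (rb1$start + rb1$end) / 2)
  }, character(1))

  ## --- purity / clonality ---------------------------------------------
  purityRows <- lapply(keep, function(id) {
    pv <- pathogenic[[id]]
    rb1v <- pv[pv$gene == "RB1", , drop = FALSE]
    if (!nrow(rb1v)) {
      return(data.frame(patient = id, purity = NA_real_,
                        mode = NA_character_, nVafs = 0L,
                        stringsAsFactors = FALSE))
    }
    v <- vaf(rb1v)
    mode <- if (any(rb1v$genotypeClass == "BB") ||
                rb1LohByTumor[[id]] == "loh") "homozygous_loh"
            else "compound_het"
    est <- purityFromVaf(v, mode)
    data.frame(patient = id, purity = est$purity, mode = mode,
               nVafs = length(v), stringsAsFactors = FALSE)
  })
  purityTab <- do.call(rbind, purityRows)
  arm16q <- arms[arms$arm == "16q", ]
  clonality <- lapply(keep, function(id) {
    p <- purityTab$purity[match(id, purityTab$patient)]
    if (is.na(p)) p <- 1
    ## amplitude measured directly from the arm's mean bin log2-ratio;
    ## independent of where the segmenter placed breakpoints
    mp <- regionPloidyFromBins(binsByTumor[[id]], arm16q$chrom,
                               arm16q$start, arm16q$end)
    if (is.na(mp)) return(NULL)
    f <- suppressWarnings(subclonalFraction(mp, p, -1L))
    data.frame(patient = id, region = "16q", observedPloidy = mp,
               purity = p, clonalFraction = f$clonalFraction,
               stringsAsFactors = FALSE)
  })
  clonalityTab <- do.call(rbind, clonality)

  ## --- driver classification ------------------------------------------
  drivers <- lapply(keep, function(id) {
    pv <- pathogenic[[id]]
    nRb1 <- length(unique(pv$pos[pv$gene == "RB1"]))
    rb1P <- segmentPloidyAt(segments[[id]], rb1$chrom, rb1$start, rb1$end)
    mycnAmp <- nrow(amps[[id]]) > 0 &&
      any(grepl("MYCN", amps[[id]]$genes))
    cls <- classifyDriver(nRb1, rb1LohByTumor[[id]] != "balanced", rb1P,
                          mycnAmp)
    data.frame(patient = id, class = cls$class,
               mycnCoAmplified = cls$mycnCoAmplified,
               rb1Snvs = nRb1, rb1Ploidy = rb1P,
               rb1Loh = rb1LohByTumor[[id]],
               stringsAsFactors = FALSE)
  })
  driverTab <- do.call(rbind, drivers)
  detected <- sum(driverTab$class != "undetermined")
  ## sensitivity relative to tumors that truly carry a detectable driver
  ## (in a cohort with ground truth); detection rate over all tumors kept
  ## alongside
  if (!is.null(truth) && nrow(truth@tumors)) {
    tmode <- truth@tumors$rb1Mode[match(driverTab$patient,
                                        truth@tumors$id)]
    hasDriver <- tmode != "none"
    detectedTrue <- sum(hasDriver &
                          driverTab$class != "undetermined")
    sensitivity <- list(
      detected = detectedTrue, total = sum(hasDriver),
      percent = percentOf(detectedTrue, max(sum(hasDriver), 1L), 0),
      detectedOverall = detected, nTumors = nrow(driverTab))
  } else {
    sensitivity <- list(
      detected = detected, total = nrow(driverTab),
      percent = percentOf(detected, nrow(driverTab), 0))
  }

  ## --- event matrix and statistics ------------------------------------
  em <- buildEventMatrix(
    keep,
    snvCalls = pathogenicAll[, c("patient", "gene")],
    armCalls = armCallsAll[, c("patient", "arm", "status")],
    chromothripsisCalls = ctAll[ctAll$chrom == "chr13",
                                c("patient", "chrom", "chromothripsis")],
    lohCalls = data.frame(patient = keep, locus = "RB1",
                          loh = rb1LohByTumor == "loh",
                          stringsAsFactors = FALSE),
    focalCalls = data.frame(
      patient = keep, event = "RB1_loss",
      present = vapply(keep, function(id) {
        p <- segmentPloidyAt(segments[[id]], rb1$chrom, rb1$start,
                             rb1$end)
        !is.na(p) && p < 0.75
      }, logical(1)), stringsAsFactors = FALSE))
  exclusivity <- testMutualExclusivity(em)
  phenoKeep <- cohort$phenotypes[cohort$phenotypes$patient %in% keep,
                                 c("patient", "ageMonths", "laterality",
                                   "heredity")]
  phenoAssoc <- testPhenotypeAssociations(em, phenoKeep)

  ## --- viral screen (optional) ----------------------------------------
  viralSummary <- NULL
  if (!is.null(viral)) {
    stopifnot(all(c("reads", "index") %in% names(viral)))
    viralSummary <- classifyReads(viral$reads, viral$index,
                                  hostIndex = viral$hostIndex)
    say("viral screen: %d of %d reads assigned", viralSummary$assigned,
        viralSummary$totalReads)
  }

  report <- list(
    qc = qc, excluded = excluded, funnel = funnel, recurrent = recurrent,
    purity = purityTab, clonality = clonalityTab, armCalls = armCallsAll,
    amplifications = ampsAll, chromothripsis = ctAll, loh = lohAll,
    drivers = driverTab, sensitivity = sensitivity, eventMatrix = em,
    exclusivity = exclusivity, phenotypeAssociations = phenoAssoc,
    viral = viralSummary, segments = segments)

  if (!is.null(outputDir)) {
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
    writeSeg(segments, file.path(outputDir, "segments.seg"))
    writeEventMatrix(em, file.path(outputDir, "event_matrix.tsv"))
    jsonlite::write_json(
      list(funnel = funnel, recurrent = recurrent,
           sensitivity = sensitivity, excluded = excluded,
           drivers = driverTab, purity = purityTab,
           clonality = clonalityTab),
      file.path(outputDir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  report
}
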