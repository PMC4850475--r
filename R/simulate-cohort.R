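## Synthetic tumor/normal cohort simulator with recorded ground truth.
##
## Every downstream stage of the package is exercised on cohorts produced
## here: somatic variants at VAFs consistent with purity and local copy
## number, binned read depths scaled by the local ploidy mixture and bent
## by a smooth GC bias, BAF markers at heterozygous germline sites, a
## phenotype table, and (optionally) viral read sets.  All randomness
## derives from the CohortSpec seed, so a fixed spec reproduces the cohort
## bit for bit.

rb1Modes <- function() {
  c("compound_het", "homozygous_snv_loh", "deletion", "mycn_amp", "none")
}

## Expected VAF of a variant on m mutated copies carried by a clonal
## fraction f of tumor cells, at purity p and local tumor copy number cT.
expectedVaf <- function(p, f, m, cT) {
  (f * p * m) / (p * cT + (1 - p) * 2)
}

## Quadratic GC bias multiplier (1 at the optimum, sagging with distance).
gcBias <- function(gc, amplitude, gcOpt = 0.45) {
  pmax(0.3, 1 - amplitude * ((gc - gcOpt) / 0.15)^2)
}

#' Generate a chromothripsis-like copy-number truth profile
#'
#' Produces alternating copy-number states confined to one chromosome:
#' losses only (states 2/1) or gains and losses (states 3/1), with
#' `nSegments` segments.  On the RB1-bearing chromosome the alternation
#' phase is chosen so the RB1 locus falls inside an altered segment.
#'
#' @param chromosome Chromosome name from the genome model.
#' @param nSegments Number of alternating segments (>= 4).
#' @param mode "losses" (default) or "mixed".
#' @param genomeModel Genome model list.
#' @param binSize Bin width the profile must be resolvable at.
#' @return data.frame: chrom, start, end, state (absolute copy number in
#'   affected cells).
#' @export
generateChromothripsisProfile <- function(chromosome, nSegments,
                                          mode = c("losses", "mixed"),
                                          genomeModel = defaultGenomeModel(),
                                          binSize = 20000L) {
  mode <- match.arg(mode)
  if (nSegments < 4L)
    stop("chromothripsis requires at least 4 alternating segments; ",
         "a flat or single-step profile is not chromothripsis")
  arms <- genomeModel$arms[genomeModel$arms$chrom == chromosome, ]
  if (!nrow(arms)) stop("unknown chromosome: ", chromosome)
  genes <- genomeModel$genes
  rb1Here <- any(genes$gene == "RB1" & genes$chrom == chromosome)
  ## shattering spans the whole chromosome (clustered alterations are
  ## chromosome-wide in this tumor type)
  region <- c(min(arms$start), max(arms$end))
  nBins <- floor((region[2] - region[1] + 1) / binSize)
  minSegBins <- 8L           # >= 160 kb at 20 kb bins: resolvable scale
  if (nSegments * minSegBins > nBins)
    stop("nSegments (", nSegments, ") exceeds the ", nBins,
         " available bins on ", chromosome)
  rb1 <- if (rb1Here)
    genes[genes$gene == "RB1" & genes$chrom == chromosome, ] else NULL
  ## segment lengths: minSegBins plus a random composition of the excess
  ## (stars-and-bars, so boundaries land on bin edges); resampled until no
  ## breakpoint interrupts the RB1 locus
  for (try in 1:100) {
    extra <- nBins - nSegments * minSegBins
    lens <- rep(minSegBins, nSegments)
    if (extra > 0L) {
      slots <- extra + nSegments - 1L
      bars <- sort(sample(slots, nSegments - 1L))
      lens <- lens + diff(c(0L, bars, slots + 1L)) - 1L
    }
    startBin <- cumsum(c(0L, head(lens, -1L)))
    start <- region[1] + startBin * binSize
    end <- region[1] + (startBin + lens) * binSize - 1L
    end[nSegments] <- region[2]
    if (is.null(rb1)) break
    contains <- start <= rb1$start & end >= rb1$end
    if (any(contains)) break
  }
  states <- if (mode == "losses") rep(c(2L, 1L), length.out = nSegments)
            else rep(c(1L, 3L), length.out = nSegments)
  prof <- data.frame(chrom = chromosome, start = start, end = end,
                     state = states, stringsAsFactors = FALSE)
  if (!is.null(rb1)) {
    inSeg <- which(prof$start <= rb1$start & prof$end >= rb1$end)
    if (length(inSeg) && prof$state[inSeg[1]] == 2L) {
      ## swap the two alternation states so RB1 sits in an altered segment
      pair <- unique(states)
      prof$state <- ifelse(prof$state == pair[1], pair[2], pair[1])
    }
  }
  prof
}

## ---------------------------------------------------------------------
## bin scaffold: coordinates, GC and mappability are deterministic
## features of the genome model (not of the sample)

binScaffold <- function(genomeModel, binSize, lowMapFraction = 0.02) {
  arms <- genomeModel$arms
  chroms <- unique(arms$chrom)
  len <- genomeModel$chromLength
  out <- lapply(chroms, function(ch) {
    start <- seq(1L, len, by = binSize)
    end <- pmin(start + binSize - 1L, len)
    ## the same positional GC profile on every chromosome, so any one
    ## chromosome-level copy change contaminates each GC stratum by at
    ## most 1/nChrom of its bins (robust trend fitting then ignores it)
    mid <- (start + end) / 2
    gc <- 0.45 + 0.08 * sin(2 * pi * mid / len * 2.5) +
      0.03 * cos(2 * pi * mid / len * 7)
    data.frame(chrom = ch, start = start, end = end, gc = round(gc, 4),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, out)
  ## a sprinkling of hard-to-map bins, fixed positions given the seed
  mapp <- rep(1, nrow(bins))
  nLow <- ceiling(lowMapFraction * nrow(bins))
  low <- sample(nrow(bins), nLow)
  mapp[low] <- runif(nLow, 0.05, 0.4)
  bins$mappability <- round(mapp, 3)
  bins
}

## tumor-cell copy number per bin given implanted events (additive) and
## chromothripsis profiles (absolute states)
tumorMixPerBin <- function(bins, events, chromoProfile, purity) {
  cT <- rep(2, nrow(bins))
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      hit <- bins$chrom == e$chrom &
        overlapWidth(bins$start, bins$end, e$start, e$end) > 0
      cT[hit] <- cT[hit] + e$clonalFraction * e$copyChange
    }
  }
  if (!is.null(chromoProfile) && nrow(chromoProfile)) {
    for (i in seq_len(nrow(chromoProfile))) {
      s <- chromoProfile[i, ]
      hit <- bins$chrom == s$chrom &
        overlapWidth(bins$start, bins$end, s$start, s$end) > 0
      cT[hit] <- s$state
    }
  }
  pmax(0, purity * cT + (1 - purity) * 2)
}

## allele-specific expected BAF at a het marker under the strongest local
## event (side = which haplotype is affected)
markerExpectedBaf <- function(p, f, copyChange, neutralLoh, sideB) {
  aN <- 1; bN <- 1                       # per-cell copies, unaffected
  if (neutralLoh) {
    aE <- if (sideB) 0 else 2
    bE <- if (sideB) 2 else 0
  } else if (copyChange < 0) {
    drop <- min(1, -copyChange)          # at most the one allele
    aE <- if (sideB) 1 else 1 - drop
    bE <- if (sideB) 1 - drop else 1
    if (copyChange <= -2) { aE <- 0; bE <- 0 }  # homozygous deletion
  } else {
    aE <- if (sideB) 1 else 1 + copyChange
    bE <- if (sideB) 1 + copyChange else 1
  }
  aTot <- p * ((1 - f) * aN + f * aE) + (1 - p) * aN
  bTot <- p * ((1 - f) * bN + f * bE) + (1 - p) * bN
  if (aTot + bTot <= 0) return(0.5)
  bTot / (aTot + bTot)
}

## ---------------------------------------------------------------------

#' Simulate a tumor/normal cohort with known ground truth
#'
#' Generates, per patient, matched tumor and normal variant tables, a
#' binned read-depth table, a BAF marker table and phenotype data, under
#' a generative model where somatic variant allele counts are binomial
#' around `f * p * m / (p * cT + (1 - p) * 2)` (purity `p`, clonal
#' fraction `f`, `m` mutated of `cT` local tumor copies), bin depths are
#' negative binomial around the local ploidy mixture bent by a smooth GC
#' bias, and BAF markers sit at sites heterozygous in the normal.
#'
#' RB1 inactivation modes are assigned per tumor (compound-heterozygous
#' SNVs, homozygous SNV after copy-neutral LOH, focal homozygous
#' deletion, MYCN amplification, or none), and recurrent arm-level copy
#' number events (16q loss, 1q/2p/6p gains) are implanted at
#' tumor-specific clonal fractions.  Age at diagnosis increases with the
#' implanted 16q clonal fraction, emulating the association between later
#' diagnosis and heavier arm-level alteration.
#'
#' @param spec A [CohortSpec-class].
#' @param rb1ModeProbs Named probabilities over RB1 inactivation modes.
#' @param armEventRates Named per-arm implant probabilities (losses are
#'   negative copy changes; see Details).
#' @param dispersion Negative-binomial dispersion of bin depths
#'   (default 0.02; variance mu + dispersion * mu^2, i.e. a per-bin depth
#'   coefficient of variation of about 17% at 100x).
#' @param gcAmplitude Amplitude of the quadratic GC bias (default 0.3).
#' @param markerSpacing BAF marker spacing in bp (default 20000).
#' @param nChromothripsis Number of tumors given 13q chromothripsis
#'   (default 2; chosen among tumors with no other RB1 mechanism).
#' @param armClonalFractionRange Interval arm-level clonal fractions are
#'   drawn from (default c(0.2, 1)).
#' @param sexMismatch Optional tumor id whose recorded sex is flipped
#'   relative to its simulated reads (QC test case).
#' @return A list: `groundTruth` ([GroundTruth-class]), `variantTables`
#'   (per tumor: list(tumor=, normal=)), `binTables`, `bafTables`,
#'   `phenotypes`, `readCounts`, `chromothripsisProfiles` (per-tumor
#'   truth state profiles), and the `spec`.
#' @export
simulateCohort <- function(spec,
                           rb1ModeProbs = c(compound_het = 0.45,
                                            homozygous_snv_loh = 0.20,
                                            deletion = 0.15,
                                            mycn_amp = 0.08,
                                            none = 0.12),
                           armEventRates = c("16q" = -0.8, "6p" = 0.68,
                                             "1q" = 0.40, "2p" = 0.30),
                           dispersion = 0.02,
                           gcAmplitude = 0.3,
                           markerSpacing = 20000L,
                           nChromothripsis = 2L,
                           armClonalFractionRange = c(0.2, 1),
                           sexMismatch = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  stopifnot(abs(sum(rb1ModeProbs) - 1) < 1e-8,
            all(names(rb1ModeProbs) %in% rb1Modes()))
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(spec@seed)

  gm <- spec@genomeModel
  arms <- gm$arms
  genes <- gm$genes
  n <- spec@nTumors
  ids <- sprintf("T%02d", seq_len(n))
  purity <- runif(n, spec@purityRange[1], spec@purityRange[2])
  mode <- sample(names(rb1ModeProbs), n, replace = TRUE,
                 prob = rb1ModeProbs)
  sex <- sample(c("male", "female"), n, replace = TRUE)

  rb1 <- genes[genes$gene == "RB1", ]
  mycn <- genes[genes$gene == "MYCN", ]
  pad <- 5L * spec@binSize                 # focal events span several bins

  events <- list(); secondary <- list(); chromo <- list()
  chromoProfiles <- setNames(vector("list", n), ids)

  ## chromothripsis of 13q acts as the alternative RB1-inactivating
  ## mechanism: implanted only in tumors with no other RB1 event
  eligible <- which(mode == "none")
  ctTumors <- if (nChromothripsis > 0L && length(eligible)) {
    sort(eligible[sample.int(length(eligible),
                             min(nChromothripsis, length(eligible)))])
  } else integer(0)

  for (i in seq_len(n)) {
    id <- ids[i]
    ## RB1 mode specific copy-number truth
    if (mode[i] == "homozygous_snv_loh") {
      q13 <- arms[arms$arm == "13q", ]
      events[[length(events) + 1L]] <- data.frame(
        tumor = id, region = "13q_cnloh", chrom = q13$chrom,
        start = q13$start, end = q13$end, copyChange = 0,
        clonalFraction = 1, neutralLoh = TRUE, stringsAsFactors = FALSE)
    } else if (mode[i] == "deletion") {
      events[[length(events) + 1L]] <- data.frame(
        tumor = id, region = "RB1_del", chrom = rb1$chrom,
        start = rb1$start - pad, end = rb1$end + pad, copyChange = -2,
        clonalFraction = 1, neutralLoh = FALSE, stringsAsFactors = FALSE)
    } else if (mode[i] == "mycn_amp") {
      events[[length(events) + 1L]] <- data.frame(
        tumor = id, region = "MYCN_amp", chrom = mycn$chrom,
        start = mycn$start - pad, end = mycn$end + pad, copyChange = 28,
        clonalFraction = 1, neutralLoh = FALSE, stringsAsFactors = FALSE)
    }
    ## recurrent arm-level events at tumor-specific clonal fractions
    for (a in names(armEventRates)) {
      rate <- abs(armEventRates[[a]])
      dir <- sign(armEventRates[[a]])
      if (runif(1) >= rate) next
      if (a == "13q" || (a == "2p" && mode[i] == "mycn_amp")) next
      if (i %in% ctTumors && a == "13q") next
      armRow <- arms[arms$arm == a, ]
      events[[length(events) + 1L]] <- data.frame(
        tumor = id, region = a, chrom = armRow$chrom,
        start = armRow$start, end = armRow$end, copyChange = dir,
        clonalFraction = runif(1, armClonalFractionRange[1],
                               armClonalFractionRange[2]),
        neutralLoh = FALSE,
        stringsAsFactors = FALSE)
    }
    if (i %in% ctTumors) {
      nSeg <- sample(10:14, 1)
      ctMode <- sample(c("losses", "mixed"), 1)
      prof <- generateChromothripsisProfile("chr13", nSeg, ctMode, gm,
                                            spec@binSize)
      chromoProfiles[[id]] <- prof
      chromo[[length(chromo) + 1L]] <- data.frame(
        tumor = id, chrom = "chr13", nSegments = nSeg, mode = ctMode,
        stringsAsFactors = FALSE)
    }
  }
  eventsDf <- if (length(events)) do.call(rbind, events) else
    data.frame(tumor = character(), region = character(),
               chrom = character(), start = integer(), end = integer(),
               copyChange = numeric(), clonalFraction = numeric(),
               neutralLoh = logical())
  chromoDf <- if (length(chromo)) do.call(rbind, chromo) else
    data.frame(tumor = character(), chrom = character(),
               nSegments = integer(), mode = character())

  ## secondary subclonal variants in BCOR / CREBBP, VAFs well below 0.5
  nBcor <- min(3L, max(1L, n %/% 3L))
  bcorT <- sample(ids, nBcor)
  pool <- setdiff(ids, bcorT)
  nCrebbp <- min(2L, length(pool))
  crebbpT <- if (nCrebbp > 0L) sample(pool, nCrebbp) else character(0)
  bcor <- genes[genes$gene == "BCOR", ]
  crebbp <- genes[genes$gene == "CREBBP", ]
  for (t in bcorT)
    secondary[[length(secondary) + 1L]] <- data.frame(
      tumor = t, gene = "BCOR", chrom = bcor$chrom,
      pos = sample(bcor$start:bcor$end, 1),
      expectedVaf = round(runif(1, 0.15, 0.45), 3),
      consequence = sample(c("stopgain", "frameshift"), 1),
      stringsAsFactors = FALSE)
  for (t in crebbpT)
    secondary[[length(secondary) + 1L]] <- data.frame(
      tumor = t, gene = "CREBBP", chrom = crebbp$chrom,
      pos = sample(crebbp$start:crebbp$end, 1),
      expectedVaf = round(runif(1, 0.15, 0.3), 3),
      consequence = "missense", stringsAsFactors = FALSE)
  secondaryDf <- do.call(rbind, secondary)

  ## phenotypes: age at diagnosis tracks the 16q clonal fraction
  f16 <- setNames(rep(0, n), ids)
  e16 <- eventsDf[eventsDf$region == "16q", ]
  f16[e16$tumor] <- e16$clonalFraction
  ageMonths <- pmax(2, round(10 + 40 * f16 + rnorm(n, 0, 5)))
  heredity <- ifelse(runif(n) < 0.4, "heritable", "non_heritable")
  laterality <- ifelse(heredity == "heritable" & runif(n) < 0.7,
                       "bilateral", "unilateral")
  recordedSex <- sex
  if (!is.null(sexMismatch)) {
    stopifnot(sexMismatch %in% ids)
    j <- match(sexMismatch, ids)
    recordedSex[j] <- setdiff(c("male", "female"), sex[j])
  }
  phenotypes <- data.frame(
    patient = ids, ageMonths = as.numeric(ageMonths),
    laterality = laterality, heredity = heredity,
    sex = recordedSex, stringsAsFactors = FALSE)

  truth <- new("GroundTruth",
    tumors = data.frame(id = ids, purity = purity, rb1Mode = mode,
                        sex = sex, ageMonths = as.numeric(ageMonths),
                        laterality = laterality, heredity = heredity,
                        stringsAsFactors = FALSE),
    events = eventsDf, secondaryVariants = secondaryDf,
    chromothripsis = chromoDf,
    viralSpike = data.frame(virus = character(), reads = integer()))

  ## ------------------------------------------------------------------
  ## per-sample tables
  scaffold <- binScaffold(gm, spec@binSize)
  bias <- gcBias(scaffold$gc, gcAmplitude)
  nbSize <- 1 / dispersion

  ## shared germline SNP panel (common population variants)
  panel <- do.call(rbind, lapply(unique(arms$chrom), function(ch) {
    pos <- seq(10000L, gm$chromLength, by = 150000L)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  panel$ref <- sample(c("A", "C", "G", "T"), nrow(panel), replace = TRUE)
  panel$alt <- vapply(panel$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  panel$popFreq <- round(runif(nrow(panel), 0.05, 0.5), 3)

  ## BAF marker scaffold (subset of sites that are het per patient)
  markerPos <- do.call(rbind, lapply(unique(arms$chrom), function(ch) {
    pos <- seq(markerSpacing %/% 2L, gm$chromLength, by = markerSpacing)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))

  variantTables <- bafTables <- binTables <- list()
  readCounts <- list()

  for (i in seq_len(n)) {
    id <- ids[i]
    p <- purity[i]
    ev <- eventsDf[eventsDf$tumor == id, , drop = FALSE]
    prof <- chromoProfiles[[id]]

    ## --- bins
    mix <- tumorMixPerBin(scaffold, ev, prof, p)
    muN <- spec@meanDepth * bias
    muT <- spec@meanDepth * bias * mix / 2
    bt <- scaffold
    bt$depthTumor <- rnbinom(nrow(bt), mu = muT, size = nbSize)
    bt$depthNormal <- rnbinom(nrow(bt), mu = muN, size = nbSize)
    binTables[[id]] <- bt

    ## --- variants
    vt <- simulateVariantTables(id, p, mode[i], ev, secondaryDf, panel,
                                rb1, spec@meanDepth)
    variantTables[[id]] <- vt

    ## --- BAF markers (het in normal)
    het <- runif(nrow(markerPos)) < 0.6
    mk <- markerPos[het, , drop = FALSE]
    baf <- numeric(nrow(mk))
    for (j in seq_len(nrow(mk))) {
      localEv <- ev[ev$chrom == mk$chrom[j] & ev$start <= mk$pos[j] &
                      ev$end >= mk$pos[j], , drop = FALSE]
      if (nrow(localEv)) {
        e <- localEv[which.max(abs(localEv$copyChange) +
                                 localEv$neutralLoh), ]
        baf[j] <- markerExpectedBaf(p, e$clonalFraction, e$copyChange,
                                    e$neutralLoh, sideB = runif(1) < 0.5)
      } else if (!is.null(prof)) {
        seg <- prof[prof$chrom == mk$chrom[j] & prof$start <= mk$pos[j] &
                      prof$end >= mk$pos[j], , drop = FALSE]
        baf[j] <- if (nrow(seg))
          markerExpectedBaf(p, 1, seg$state[1] - 2L, FALSE,
                            sideB = runif(1) < 0.5) else 0.5
      } else baf[j] <- 0.5
    }
    depth <- rpois(nrow(mk), spec@meanDepth)
    obs <- ifelse(depth > 0, rbinom(nrow(mk), depth, baf) / pmax(depth, 1),
                  NA_real_)
    bafTables[[id]] <- data.frame(
      sample = id, chrom = mk$chrom, pos = mk$pos, depth = depth,
      baf = obs, genotypeNormal = "AB", stringsAsFactors = FALSE)

    ## --- chromosome read counts (sex QC)
    auto <- spec@meanDepth * gm$chromLength / 100
    rc <- setNames(rpois(length(unique(arms$chrom)), auto),
                   unique(arms$chrom))
    yMu <- sum(rc) * if (sex[i] == "male") 0.002 else 1e-4
    rc <- c(rc, chrY = rpois(1, yMu))
    readCounts[[id]] <- rc
  }

  list(groundTruth = truth, variantTables = variantTables,
       binTables = binTables, bafTables = bafTables,
       phenotypes = phenotypes, readCounts = readCounts,
       chromothripsisProfiles = chromoProfiles[
         !vapply(chromoProfiles, is.null, logical(1))],
       spec = spec)
}

## tumor + normal variant tables for one patient
simulateVariantTables <- function(id, p, mode, ev, secondaryDf, panel, rb1,
                                  meanDepth) {
  blank <- function(nr) data.frame(
    patient = rep(id, nr), chrom = character(nr), pos = integer(nr),
    ref = character(nr), alt = character(nr),
    genotypeClass = character(nr), depth = integer(nr),
    altDepth = integer(nr), qual = numeric(nr), fs = numeric(nr),
    filterFlag = character(nr), popFreqEsp = numeric(nr),
    popFreq1kg = numeric(nr), consequence = character(nr),
    pred1 = character(nr), pred2 = character(nr), pred3 = character(nr),
    pred4 = character(nr), gene = character(nr), stringsAsFactors = FALSE)

  ## germline panel subset carried by this patient
  carry <- runif(nrow(panel)) < 0.6
  g <- panel[carry, , drop = FALSE]
  gHom <- runif(nrow(g)) < 0.15
  nG <- nrow(g)
  gDepthN <- rpois(nG, meanDepth)
  gAltN <- rbinom(nG, gDepthN, ifelse(gHom, 0.995, 0.5))
  normal <- blank(nG)
  normal$chrom <- g$chrom; normal$pos <- g$pos
  normal$ref <- g$ref; normal$alt <- g$alt
  normal$genotypeClass <- ifelse(gHom, "BB", "AB")
  normal$depth <- gDepthN; normal$altDepth <- pmin(gAltN, gDepthN)
  normal$qual <- round(runif(nG, 100, 3000), 1)
  normal$fs <- round(runif(nG, 0, 15), 2)
  normal$filterFlag <- "PASS"
  normal$popFreqEsp <- g$popFreq; normal$popFreq1kg <- g$popFreq
  normal$consequence <- "synonymous"
  normal[c("pred1", "pred2", "pred3", "pred4")] <- "benign"
  normal$gene <- ""

  ## tumor re-observes the germline variants (same genotype class)
  tumor <- normal
  tDepth <- rpois(nG, meanDepth)
  tumor$depth <- tDepth
  tumor$altDepth <- rbinom(nG, tDepth, ifelse(gHom, 0.995, 0.5))

  somaticRow <- function(chrom, pos, gene, vafExp, consequence,
                         preds = c("pathogenic", "pathogenic",
                                   "benign", "benign")) {
    d <- max(10L, rpois(1, meanDepth))
    a <- rbinom(1, d, min(1, vafExp))
    row <- blank(1)
    row$chrom <- chrom; row$pos <- as.integer(pos)
    row$ref <- "C"; row$alt <- "T"
    row$genotypeClass <- genotypeClassFromVaf(a / d)
    row$depth <- d; row$altDepth <- a
    row$qual <- round(runif(1, 200, 3000), 1)
    row$fs <- round(runif(1, 0, 10), 2)
    row$filterFlag <- "PASS"
    row$popFreqEsp <- 0; row$popFreq1kg <- 0
    row$consequence <- consequence
    row[c("pred1", "pred2", "pred3", "pred4")] <- as.list(preds)
    row$gene <- gene
    row
  }

  som <- list()
  if (mode == "compound_het") {
    pos1 <- sample(rb1$start:rb1$end, 2)
    vafExp <- expectedVaf(p, 1, 1, 2)
    som[[1]] <- somaticRow(rb1$chrom, pos1[1], "RB1", vafExp, "stopgain")
    som[[2]] <- somaticRow(rb1$chrom, pos1[2], "RB1", vafExp, "frameshift")
  } else if (mode == "homozygous_snv_loh") {
    vafExp <- expectedVaf(p, 1, 2, 2)
    som[[1]] <- somaticRow(rb1$chrom, sample(rb1$start:rb1$end, 1),
                           "RB1", vafExp, "stopgain")
  }
  sec <- secondaryDf[secondaryDf$tumor == id, , drop = FALSE]
  if (nrow(sec)) {
    for (j in seq_len(nrow(sec))) {
      preds <- if (sec$consequence[j] == "missense")
        c("pathogenic", "pathogenic", "pathogenic", "benign")
      else c("pathogenic", "pathogenic", "benign", "benign")
      som[[length(som) + 1L]] <- somaticRow(
        sec$chrom[j], sec$pos[j], sec$gene[j], sec$expectedVaf[j],
        sec$consequence[j], preds)
    }
  }
  if (length(som)) tumor <- rbind(tumor, do.call(rbind, som))
  tumor <- tumor[order(tumor$chrom, tumor$pos), , drop = FALSE]
  rownames(tumor) <- rownames(normal) <- NULL
  list(tumor = tumor, normal = normal)
}
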