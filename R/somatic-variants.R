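## Somatic SNV/INDEL identification and pathogenicity filtering.
##
## Variant tables are plain data.frames with one row per (decomposed)
## alternate allele and the columns listed in variantColumns().  The filter
## chain is a monotone pipeline: quality filter -> subtraction against the
## pooled germline database -> pathogenicity filter -> recurrence.

variantColumns <- function() {
  c("patient", "chrom", "pos", "ref", "alt", "genotypeClass", "depth",
    "altDepth", "qual", "fs", "filterFlag", "popFreqEsp", "popFreq1kg",
    "consequence", "pred1", "pred2", "pred3", "pred4", "gene")
}

truncatingConsequences <- function() {
  c("stopgain", "stoploss", "frameshift", "nonframeshift_indel", "splice")
}

checkVariantTable <- function(records) {
  missing <- setdiff(variantColumns(), names(records))
  if (length(missing))
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  bad <- records$altDepth > records$depth
  if (any(bad, na.rm = TRUE)) stop("altDepth exceeds depth")
  invisible(records)
}

#' Variant allele frequency of variant records
#'
#' The fraction of reads at a site supporting the variant allele,
#' `altDepth / depth` — the quantity from which tumor cellularity and
#' mutation clonality are read off.
#'
#' @param records Variant data.frame with `altDepth` and `depth` columns.
#' @return Numeric vector of VAFs.
#' @examples
#' vaf(data.frame(altDepth = 33, depth = 36))  # 0.9167
#' @export
vaf <- function(records) {
  stopifnot(all(c("altDepth", "depth") %in% names(records)))
  if (any(records$depth <= 0))
    stop("VAF undefined at zero depth")
  records$altDepth / records$depth
}

#' Genotype class from VAF
#'
#' Assigns AA / AB / BB by comparing the VAF with a homozygosity threshold:
#' BB when `vaf >= hom`, AB when `het <= vaf < hom`, else AA.  Used when a
#' caller's genotype field is absent; the homozygous threshold is exposed
#' because hard thresholds are known to misclassify true somatic variants
#' with VAF just below it.
#'
#' @param v Numeric VAFs.
#' @param het Lower bound for heterozygous calls (default 0.15).
#' @param hom Lower bound for homozygous-variant calls (default 0.85).
#' @return Character vector in \{"AA", "AB", "BB"\}.
#' @export
genotypeClassFromVaf <- function(v, het = 0.15, hom = 0.85) {
  assertFraction(v, "vaf")
  ifelse(v >= hom, "BB", ifelse(v >= het, "AB", "AA"))
}

#' Basic variant quality filter
#'
#' Discards variant calls with low coverage (depth < 5 reads), low variant
#' quality (QUAL < 50) or strand bias (Fisher strand-bias Phred score
#' > 60); all three inequalities are strict, so a record at depth 5,
#' QUAL 50 or FS 60 is kept.  Records missing any of the three fields are
#' rejected (with a reason attribute).
#'
#' @param records Variant data.frame.
#' @param minDepth Records with depth below this are discarded (default 5).
#' @param minQual Records with QUAL below this are discarded (default 50).
#' @param maxFs Records with strand-bias score above this are discarded
#'   (default 60).
#' @return The retained subset, with a `rejected` attribute holding a
#'   data.frame of discarded rows and the reason.
#' @export
qualityFilter <- function(records, minDepth = 5, minQual = 50, maxFs = 60) {
  stopifnot(all(c("depth", "qual", "fs") %in% names(records)))
  reason <- rep(NA_character_, nrow(records))
  incomplete <- is.na(records$depth) | is.na(records$qual) |
    is.na(records$fs)
  reason[incomplete] <- "missing_field"
  reason[!incomplete & records$depth < minDepth] <- "low_depth"
  reason[!incomplete & is.na(reason) & records$qual < minQual] <- "low_qual"
  reason[!incomplete & is.na(reason) & records$fs > maxFs] <- "strand_bias"
  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  attr(out, "rejected") <- cbind(records[!keep, , drop = FALSE],
                                 reason = reason[!keep])
  out
}

variantKey <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt,
        records$genotypeClass, sep = ":")
}

#' Build the pooled germline variant database
#'
#' Merges the variant tables of all sequenced normals into a single
#' anonymized database: the union of (chrom, pos, ref, alt, genotype
#' class) keys with no per-patient attribution.  The same site and alleles
#' carried as AB in one normal and BB in another yields two distinct keys.
#'
#' @param normalTables List of (or a single) normal variant data.frames.
#' @return A [GermlineDB-class].
#' @export
buildGermlineDb <- function(normalTables) {
  if (is.data.frame(normalTables)) normalTables <- list(normalTables)
  stopifnot(length(normalTables) >= 1L)
  keys <- unlist(lapply(normalTables, function(tab) {
    if (!nrow(tab)) return(character())
    variantKey(tab)
  }), use.names = FALSE)
  new("GermlineDB", keys = sort(unique(keys)))
}

#' Identify somatic variants by pooled-germline subtraction
#'
#' Retains quality-filtered tumor variants whose key — genomic
#' coordinates, reference and mutant allele, and genotype class — is not
#' recorded in the pooled germline database, provided they are covered by
#' at least `minDepth` reads (default 10).  Because the key includes the
#' genotype class, a site carried as AB in the germline pool but called BB
#' in the tumor is retained: the tumor genotype is a different key.
#'
#' @param tumorRecords Quality-filtered tumor variant data.frame.
#' @param db A [GermlineDB-class] from [buildGermlineDb()].
#' @param minDepth Minimum read depth for a somatic call (default 10).
#' @return The somatic subset of `tumorRecords`.
#' @export
callSomatic <- function(tumorRecords, db, minDepth = 10) {
  stopifnot(is(db, "GermlineDB"))
  if (!nrow(tumorRecords)) return(tumorRecords)
  keep <- !(variantKey(tumorRecords) %in% db@keys) &
    tumorRecords$depth >= minDepth
  tumorRecords[keep, , drop = FALSE]
}

#' Filter somatic variants for possible pathogenicity
#'
#' Retains somatic variants that are rare in both reference populations
#' (frequency strictly below `maxPopFreq` in each), are marked PASS by the
#' caller, and are either truncating (stop-gain/loss, frameshift or
#' non-frameshift INDELs) or splice-site mutations, or amino-acid
#' substitutions scored pathogenic by at least `minPredictors` of the four
#' pathogenicity predictors.  Missing predictor annotations count as
#' non-pathogenic votes.
#'
#' @param records Somatic variant data.frame.
#' @param maxPopFreq Strict population-frequency upper bound
#'   (default 0.001, i.e. < 0.1%).
#' @param minPredictors Minimum pathogenic predictor votes for missense
#'   variants (default 2 of 4).
#' @return The retained subset.
#' @export
pathogenicityFilter <- function(records, maxPopFreq = 0.001,
                                minPredictors = 2L) {
  need <- c("popFreqEsp", "popFreq1kg", "filterFlag", "consequence",
            "pred1", "pred2", "pred3", "pred4")
  stopifnot(all(need %in% names(records)))
  if (!nrow(records)) return(records)
  rare <- records$popFreqEsp < maxPopFreq & records$popFreq1kg < maxPopFreq
  pass <- records$filterFlag == "PASS"
  truncating <- records$consequence %in% truncatingConsequences()
  votes <- rowSums(
    cbind(records$pred1, records$pred2, records$pred3,
          records$pred4) == "pathogenic",
    na.rm = TRUE)
  damagingMissense <- records$consequence == "missense" &
    votes >= minPredictors
  records[rare & pass & (truncating | damagingMissense), , drop = FALSE]
}

#' Recurrently mutated genes
#'
#' Counts, per gene, the number of distinct patients carrying at least one
#' filtered somatic variant, and reports genes mutated in at least
#' `minPatients` different patients.  Multiple variants of one gene in the
#' same patient count once.
#'
#' @param records Filtered somatic variant data.frame with `patient` and
#'   `gene` columns.
#' @param minPatients Recurrence threshold (default 2 distinct patients).
#' @return data.frame (gene, nPatients, nVariants) sorted by decreasing
#'   patient count; zero rows when nothing recurs.
#' @export
recurrentGenes <- function(records, minPatients = 2L) {
  stopifnot(all(c("patient", "gene") %in% names(records)))
  if (!nrow(records)) {
    return(data.frame(gene = character(), nPatients = integer(),
                      nVariants = integer()))
  }
  byGene <- split(records$patient, records$gene)
  df <- data.frame(
    gene = names(byGene),
    nPatients = vapply(byGene, function(p) length(unique(p)), integer(1)),
    nVariants = vapply(byGene, length, integer(1)),
    stringsAsFactors = FALSE
  )
  df <- df[df$nPatients >= minPatients, , drop = FALSE]
  df <- df[order(-df$nPatients, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-stage counts of the somatic filter funnel
#'
#' Summarises how many variant records survive each stage of the chain
#' (total called, quality-filtered, somatic, possibly pathogenic) together
#' with the retained percentage relative to the previous stage.
#'
#' @param total,afterQuality,somatic,pathogenic Stage record counts.
#' @return data.frame: stage, count, percentOfPrevious.
#' @export
variantFunnel <- function(total, afterQuality, somatic, pathogenic) {
  counts <- c(total = total, afterQuality = afterQuality,
              somatic = somatic, pathogenic = pathogenic)
  if (any(diff(counts) > 0))
    stop("funnel counts must be non-increasing")
  pct <- rep(NA_real_, length(counts))
  for (i in seq_along(counts)[-1]) {
    if (counts[i - 1L] > 0) pct[i] <- percentOf(counts[i], counts[i - 1L])
  }
  data.frame(
    stage = names(counts),
    count = as.integer(counts),
    percentOfPrevious = pct,
    row.names = NULL
  )
}
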