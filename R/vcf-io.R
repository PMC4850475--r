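## VCF 4.2 emission for simulated variant tables and reading back through
## VariantAnnotation.  Annotations travel as INFO keys (DP, AO, FS,
## POPFREQ_ESP, POPFREQ_1KG, CONSEQ, PRED1..PRED4, GENE, GTC); the variant
## quality is the QUAL column and the caller flag the FILTER column.

vcfInfoHeader <- function() {
  c('##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=AO,Number=1,Type=Integer,Description="Alternate allele read count">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Phred-scaled Fisher strand bias">',
    '##INFO=<ID=POPFREQ_ESP,Number=1,Type=Float,Description="Population frequency, exome panel">',
    '##INFO=<ID=POPFREQ_1KG,Number=1,Type=Float,Description="Population frequency, 1000 genomes">',
    '##INFO=<ID=CONSEQ,Number=1,Type=String,Description="Functional consequence">',
    '##INFO=<ID=PRED1,Number=1,Type=String,Description="Pathogenicity predictor 1">',
    '##INFO=<ID=PRED2,Number=1,Type=String,Description="Pathogenicity predictor 2">',
    '##INFO=<ID=PRED3,Number=1,Type=String,Description="Pathogenicity predictor 3">',
    '##INFO=<ID=PRED4,Number=1,Type=String,Description="Pathogenicity predictor 4">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=GTC,Number=1,Type=String,Description="Genotype class (AA/AB/BB)">')
}

#' Write a variant table as VCF 4.2
#'
#' @param records Variant data.frame (see the somatic-variant module for
#'   the expected columns).
#' @param file Output path.
#' @param sampleId Sample identifier recorded in the header.
#' @return The path, invisibly.
#' @export
writeVariantVcf <- function(records, file, sampleId = "sample") {
  checkVariantTable(records)
  dotIf <- function(x) ifelse(is.na(x) | x == "", ".", as.character(x))
  info <- sprintf(
    "DP=%d;AO=%d;FS=%s;POPFREQ_ESP=%s;POPFREQ_1KG=%s;CONSEQ=%s;PRED1=%s;PRED2=%s;PRED3=%s;PRED4=%s;GENE=%s;GTC=%s",
    records$depth, records$altDepth, format(records$fs, trim = TRUE),
    format(records$popFreqEsp, trim = TRUE, scientific = FALSE),
    format(records$popFreq1kg, trim = TRUE, scientific = FALSE),
    dotIf(records$consequence), dotIf(records$pred1), dotIf(records$pred2),
    dotIf(records$pred3), dotIf(records$pred4), dotIf(records$gene),
    dotIf(records$genotypeClass))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                format(records$qual, trim = TRUE),
                records$filterFlag, info, sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              paste0("##source=rbscape;sample=", sampleId),
              vcfInfoHeader(),
              '##FILTER=<ID=lowqual,Description="Failed caller filters">',
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a VCF into the package's variant table layout
#'
#' Parses a VCF 4.2 file through `VariantAnnotation::readVcf` and maps
#' the INFO annotations back onto the flat variant table the filter chain
#' consumes.  Multi-allelic records are decomposed into one row per
#' alternate allele by the underlying expansion.
#'
#' @param file VCF path.
#' @param patient Patient identifier attached to every row.
#' @return Variant data.frame.
#' @export
readVariantVcf <- function(file, patient = NA_character_) {
  v <- VariantAnnotation::readVcf(file, genome = "synthetic")
  v <- VariantAnnotation::expand(v)
  rr <- SummarizedExperiment::rowRanges(v)
  info <- VariantAnnotation::info(v)
  asChr <- function(x) {
    x <- as.character(x)
    x[x == "."] <- NA_character_
    x
  }
  df <- data.frame(
    patient = patient,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    genotypeClass = asChr(info$GTC),
    depth = as.integer(info$DP),
    altDepth = as.integer(info$AO),
    qual = as.numeric(rr$QUAL),
    fs = as.numeric(info$FS),
    filterFlag = as.character(rr$FILTER),
    popFreqEsp = as.numeric(info$POPFREQ_ESP),
    popFreq1kg = as.numeric(info$POPFREQ_1KG),
    consequence = asChr(info$CONSEQ),
    pred1 = asChr(info$PRED1), pred2 = asChr(info$PRED2),
    pred3 = asChr(info$PRED3), pred4 = asChr(info$PRED4),
    gene = asChr(info$GENE),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write simulated cohort artifacts to a directory
#'
#' Emits, per patient, tumor and normal VCFs, a bin TSV and a BAF marker
#' TSV, plus the cohort phenotype TSV and a JSON ground-truth sidecar.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param cohort Output of [simulateCohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, path)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$variantTables)) {
    vt <- cohort$variantTables[[id]]
    writeVariantVcf(vt$tumor, file.path(dir, paste0(id, "_tumor.vcf")), id)
    writeVariantVcf(vt$normal, file.path(dir, paste0(id, "_normal.vcf")),
                    paste0(id, "N"))
    tsv(cohort$binTables[[id]], file.path(dir, paste0(id, "_bins.tsv")))
    tsv(cohort$bafTables[[id]], file.path(dir, paste0(id, "_baf.tsv")))
  }
  tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  gt <- cohort$groundTruth
  jsonlite::write_json(
    list(tumors = gt@tumors, events = gt@events,
         secondaryVariants = gt@secondaryVariants,
         chromothripsis = gt@chromothripsis, viralSpike = gt@viralSpike),
    file.path(dir, "ground_truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
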