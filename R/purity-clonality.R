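## Tumor purity from driver VAFs; subclonal fractions from copy-number
## amplitudes under a two-population mixture with a diploid background.

#' Estimate tumor purity from driver-gene VAFs
#'
#' In a tumor whose driver gene is inactivated by two heterozygous hits
#' (compound heterozygous; one mutated copy of a diploid locus) each hit
#' has expected VAF purity/2, so purity is twice the mean VAF.  When the
#' driver is homozygously mutated after copy-neutral LOH, both copies are
#' mutated and purity equals the mean VAF directly.  Estimates are clamped
#' into \[0, 1\] with a warning, since read-sampling noise can push the raw
#' value slightly outside.
#'
#' @param vafs Numeric vector of VAFs of the driver variants (>= 1).
#' @param mode `"compound_het"` or `"homozygous_loh"`.
#' @return list: tumor purity estimate (`purity`), `mode`, supporting
#'   `vafs`.
#' @examples
#' purityFromVaf(c(0.49, 0.47), "compound_het")  # ~0.96
#' @export
purityFromVaf <- function(vafs, mode = c("compound_het", "homozygous_loh")) {
  mode <- match.arg(mode)
  stopifnot(length(vafs) >= 1L, all(is.finite(vafs)))
  assertFraction(vafs, "vafs")
  raw <- switch(mode,
                compound_het = 2 * mean(vafs),
                homozygous_loh = mean(vafs))
  if (raw > 1 || raw < 0)
    warning("purity estimate ", round(raw, 3), " clamped into [0, 1]")
  list(purity = min(1, max(0, raw)), mode = mode, vafs = vafs)
}

#' Subclonal fraction of a copy-number event from its amplitude
#'
#' Models the observed mean ploidy of a region as a mixture of normal
#' cells (diploid), tumor cells without the event (diploid) and tumor
#' cells carrying a copy change of `copyChange`:
#' `observed = p * (2 + f * copyChange) + (1 - p) * 2`, hence
#' `f = (observed - 2) / (p * copyChange)`.  A one-copy loss observed at
#' mean ploidy 1.5 in a pure tumor therefore involves half the tumor
#' cells.  Estimates are clamped into \[0, 1\] with a warning.
#'
#' @param observedPloidy Mean ploidy of the region (from segment LRRs).
#' @param purity Tumor purity in (0, 1].
#' @param copyChange Integer copy change in the affected cells (e.g. -1
#'   for a one-copy loss, +1 for a gain); must be non-zero.
#' @return list: `clonalFraction`, `observedPloidy`, `purity`,
#'   `copyChange`.
#' @examples
#' subclonalFraction(1.5, purity = 1, copyChange = -1)  # f = 0.5
#' @export
subclonalFraction <- function(observedPloidy, purity, copyChange) {
  stopifnot(is.finite(observedPloidy), copyChange != 0)
  if (purity <= 0 || purity > 1)
    stop("purity must lie in (0, 1]")
  raw <- (observedPloidy - 2) / (purity * copyChange)
  if (raw > 1 || raw < 0)
    warning("clonal fraction estimate ", round(raw, 3),
            " clamped into [0, 1]")
  list(clonalFraction = min(1, max(0, raw)),
       observedPloidy = observedPloidy, purity = purity,
       copyChange = copyChange)
}

#' Rank correlation between event amplitude and age at diagnosis
#'
#' Kendall's tau-b (tie-corrected) between a per-tumor copy-number
#' amplitude (e.g. depth of 16q loss) and age at diagnosis, with the
#' two-sided p-value of Kendall's rank correlation test.
#'
#' @param amplitude Numeric per-tumor amplitudes.
#' @param age Numeric ages at diagnosis, same length.
#' @return list: `tau`, `pValue`, `n`.
#' @export
amplitudeAgeCorrelation <- function(amplitude, age) {
  stopifnot(length(amplitude) == length(age), length(age) >= 3L)
  if (sd(amplitude) == 0 || sd(age) == 0)
    stop("Kendall's tau undefined for a constant vector")
  ct <- suppressWarnings(
    cor.test(amplitude, age, method = "kendall", exact = FALSE))
  list(tau = unname(cor(amplitude, age, method = "kendall")),
       pValue = ct$p.value, n = length(age))
}
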