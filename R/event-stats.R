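## Binary somatic event matrix and its association statistics.

#' Assemble the binary somatic event matrix
#'
#' Combines per-tumor call sets into a tumors-by-events 0/1/NA matrix:
#' gene SNV/INDEL rows from the filtered somatic calls, arm-level rows
#' from mean-ploidy threshold calls, plus chromothripsis and LOH-at-locus
#' rows.  A tumor absent from an upstream call set gets NA (data not
#' available) for the corresponding rows.
#'
#' @param tumors Character vector of tumor identifiers (matrix columns).
#' @param snvCalls data.frame (patient, gene) of filtered somatic
#'   variants, or NULL.
#' @param snvGenes Genes to materialise as SNV rows (default: all genes
#'   present in `snvCalls`).
#' @param armCalls data.frame (patient, arm, status) of arm-level calls,
#'   or NULL; status "gain"/"loss" maps to 1 for the corresponding row.
#' @param chromothripsisCalls data.frame (patient, chrom, chromothripsis),
#'   or NULL.
#' @param lohCalls data.frame (patient, locus, loh: logical), or NULL.
#' @param focalCalls data.frame (patient, event, present: logical) for
#'   focal amplification/deletion rows, or NULL.
#' @return An [EventMatrix-class].
#' @export
buildEventMatrix <- function(tumors, snvCalls = NULL, snvGenes = NULL,
                             armCalls = NULL, chromothripsisCalls = NULL,
                             lohCalls = NULL, focalCalls = NULL) {
  stopifnot(length(tumors) >= 1L, !anyDuplicated(tumors))
  rows <- list()
  checkIds <- function(df, what) {
    extra <- setdiff(df$patient, tumors)
    if (length(extra))
      stop(what, " carries unknown tumor identifiers: ",
           paste(extra, collapse = ", "))
  }
  if (!is.null(snvCalls) && nrow(snvCalls)) {
    checkIds(snvCalls, "snvCalls")
    genes <- snvGenes %||% sort(unique(snvCalls$gene))
    for (g in genes) {
      v <- setNames(rep(0L, length(tumors)), tumors)
      v[unique(snvCalls$patient[snvCalls$gene == g])] <- 1L
      rows[[paste0(g, "_snv")]] <- v
    }
  }
  if (!is.null(armCalls) && nrow(armCalls)) {
    checkIds(armCalls, "armCalls")
    ## an arm is "altered" when its mean ploidy crossed either threshold
    for (a in sort(unique(armCalls$arm))) {
      sub <- armCalls[armCalls$arm == a, , drop = FALSE]
      v <- setNames(rep(NA_integer_, length(tumors)), tumors)
      v[sub$patient] <- ifelse(is.na(sub$status), NA_integer_,
                               as.integer(sub$status %in% c("gain", "loss")))
      rows[[paste0(a, "_scna")]] <- v
    }
  }
  if (!is.null(chromothripsisCalls) && nrow(chromothripsisCalls)) {
    checkIds(chromothripsisCalls, "chromothripsisCalls")
    for (ch in sort(unique(chromothripsisCalls$chrom))) {
      sub <- chromothripsisCalls[chromothripsisCalls$chrom == ch, ,
                                 drop = FALSE]
      v <- setNames(rep(NA_integer_, length(tumors)), tumors)
      v[sub$patient] <- as.integer(sub$chromothripsis)
      rows[[paste0("chromothripsis_", sub("chr", "", ch))]] <- v
    }
  }
  if (!is.null(lohCalls) && nrow(lohCalls)) {
    checkIds(lohCalls, "lohCalls")
    for (loc in sort(unique(lohCalls$locus))) {
      sub <- lohCalls[lohCalls$locus == loc, , drop = FALSE]
      v <- setNames(rep(NA_integer_, length(tumors)), tumors)
      v[sub$patient] <- as.integer(sub$loh)
      rows[[paste0(loc, "_loh")]] <- v
    }
  }
  if (!is.null(focalCalls) && nrow(focalCalls)) {
    checkIds(focalCalls, "focalCalls")
    for (ev in sort(unique(focalCalls$event))) {
      sub <- focalCalls[focalCalls$event == ev, , drop = FALSE]
      v <- setNames(rep(NA_integer_, length(tumors)), tumors)
      v[sub$patient] <- as.integer(sub$present)
      rows[[ev]] <- v
    }
  }
  if (!length(rows)) stop("no events to assemble")
  m <- do.call(rbind, rows)
  colnames(m) <- tumors
  EventMatrix(m)
}

#' Phi correlation coefficient of a 2x2 contingency table
#'
#' `phi = (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)` — the Pearson
#' correlation of the two binary variables.  Negative values indicate
#' mutual exclusivity.  Undefined (NA) when any margin is zero.
#'
#' @param n11,n10,n01,n00 Cell counts: n11 both events present, n10 only
#'   the first, n01 only the second, n00 neither.
#' @return Phi in \[-1, 1\], or NA when a margin is empty.
#' @examples
#' phiCoefficient(5, 0, 0, 5)   #  1: perfect co-occurrence
#' phiCoefficient(0, 5, 5, 0)   # -1: perfect exclusivity
#' @export
phiCoefficient <- function(n11, n10, n01, n00) {
  stopifnot(all(c(n11, n10, n01, n00) >= 0))
  r1 <- n11 + n10; r0 <- n01 + n00
  c1 <- n11 + n01; c0 <- n10 + n00
  if (r1 == 0 || r0 == 0 || c1 == 0 || c0 == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / sqrt(r1 * r0 * c1 * c0)
}

#' Pairwise mutual-exclusivity / co-occurrence testing
#'
#' For every pair of events with both states observed (complete cases
#' only; no imputation of missing entries), computes the phi coefficient
#' of the 2x2 table and a two-sided Fisher exact p-value, then applies
#' Benjamini-Hochberg correction across all tested pairs.
#'
#' @param em An [EventMatrix-class] or 0/1/NA matrix (rows = events).
#' @param method Significance test: "fisher" (default) or "chisq".
#' @param fdrAlpha Significance level on the q-value used for the
#'   `significant` flag (default 0.05).
#' @return data.frame per tested pair: eventA, eventB, n (complete
#'   cases), n11/n10/n01/n00, phi, pValue, qValue, direction
#'   ("co-occurrence"/"exclusivity"), significant.
#' @export
testMutualExclusivity <- function(em, method = c("fisher", "chisq"),
                                  fdrAlpha = 0.05) {
  method <- match.arg(method)
  m <- if (is(em, "EventMatrix")) eventMatrix(em) else em
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  pairs <- utils::combn(nrow(m), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- m[i1, ]; b <- m[i2, ]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) return(NULL)
    n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
    n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
    tab <- matrix(c(n11, n01, n10, n00), 2)
    p <- if (method == "fisher") fisher.test(tab)$p.value
         else suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
    phi <- phiCoefficient(n11, n10, n01, n00)
    data.frame(eventA = rownames(m)[i1], eventB = rownames(m)[i2],
               n = length(a), n11 = n11, n10 = n10, n01 = n01, n00 = n00,
               phi = phi, pValue = p,
               direction = ifelse(phi < 0, "exclusivity", "co-occurrence"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(eventA = character(), eventB = character(),
                      n = integer(), n11 = integer(), n10 = integer(),
                      n01 = integer(), n00 = integer(), phi = numeric(),
                      pValue = numeric(), qValue = numeric(),
                      direction = character(), significant = logical()))
  }
  res$qValue <- p.adjust(res$pValue, method = "BH")
  res$significant <- res$qValue < fdrAlpha
  res[order(res$qValue, res$pValue), ]
}

#' Event-phenotype association testing
#'
#' Tests every event row against every phenotype column: binary event
#' versus a continuous phenotype with a two-sided Wilcoxon rank-sum test
#' (direction from the difference of group medians), versus a categorical
#' phenotype with a Fisher exact test on the contingency table.
#' Benjamini-Hochberg correction is applied separately per phenotype.
#' Constant phenotypes (or events with one observed state) are skipped.
#'
#' @param em An [EventMatrix-class] or 0/1/NA matrix.
#' @param phenotypes data.frame, one row per tumor, rownames (or a
#'   `patient` column) matching the matrix columns; numeric columns are
#'   treated as continuous, everything else as categorical.
#' @param fdrAlpha Significance level on the q-value (default 0.05).
#' @return data.frame: event, phenotype, test, n, statistic, pValue,
#'   qValue, direction, significant.
#' @export
testPhenotypeAssociations <- function(em, phenotypes, fdrAlpha = 0.05) {
  m <- if (is(em, "EventMatrix")) eventMatrix(em) else em
  if ("patient" %in% names(phenotypes)) {
    rownames(phenotypes) <- phenotypes$patient
    phenotypes$patient <- NULL
  }
  stopifnot(all(colnames(m) %in% rownames(phenotypes)))
  phenotypes <- phenotypes[colnames(m), , drop = FALSE]
  out <- list()
  for (ph in names(phenotypes)) {
    pv <- phenotypes[[ph]]
    rows <- lapply(rownames(m), function(ev) {
      e <- m[ev, ]
      ok <- !is.na(e) & !is.na(pv)
      e <- e[ok]; p <- pv[ok]
      if (length(unique(e)) < 2L) return(NULL)
      if (is.numeric(p)) {
        if (sd(p) == 0) return(NULL)
        wt <- suppressWarnings(wilcox.test(p[e == 1], p[e == 0]))
        med1 <- median(p[e == 1]); med0 <- median(p[e == 0])
        data.frame(event = ev, phenotype = ph, test = "ranksum",
                   n = length(e), statistic = unname(wt$statistic),
                   pValue = wt$p.value,
                   direction = if (med1 > med0) "higher"
                               else if (med1 < med0) "lower" else "none",
                   stringsAsFactors = FALSE)
      } else {
        p <- as.factor(as.character(p))
        if (nlevels(p) < 2L) return(NULL)
        tab <- table(factor(e, levels = c(0, 1)), p)
        ft <- fisher.test(tab)
        data.frame(event = ev, phenotype = ph, test = "fisher",
                   n = length(e), statistic = NA_real_,
                   pValue = ft$p.value, direction = "association",
                   stringsAsFactors = FALSE)
      }
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows)) {
      rows$qValue <- p.adjust(rows$pValue, method = "BH")
      out[[ph]] <- rows
    }
  }
  if (!length(out)) {
    return(data.frame(event = character(), phenotype = character(),
                      test = character(), n = integer(),
                      statistic = numeric(), pValue = numeric(),
                      direction = character(), qValue = numeric(),
                      significant = logical()))
  }
  res <- do.call(rbind, out)
  res$significant <- res$qValue < fdrAlpha
  rownames(res) <- NULL
  res
}

#' Serialize / deserialize an event matrix as TSV
#'
#' Round-trips the 0/1/NA matrix losslessly (missing entries written as
#' NA), events as rows and tumors as columns.
#'
#' @param em An [EventMatrix-class].
#' @param file Path to write to / read from.
#' @return `writeEventMatrix` the path invisibly; `readEventMatrix` an
#'   [EventMatrix-class].
#' @export
writeEventMatrix <- function(em, file) {
  m <- eventMatrix(em)
  df <- data.frame(event = rownames(m), m, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeEventMatrix
#' @export
readEventMatrix <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$event
  EventMatrix(m)
}
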