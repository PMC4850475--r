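#' @importFrom stats median rbinom rnorm rpois rnbinom runif setNames
#'   fisher.test wilcox.test cor cor.test p.adjust sd loess predict quantile
#' @importFrom methods new validObject is slot
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

utils::globalVariables(c(".", ".I", ".N", "N", "virus", "refPos",
                         "readPos", "diag", "kmer"))

#' Express a count as a printed percentage
#'
#' Small reporting helper used throughout the cohort report to turn
#' numerator/denominator pairs into the percentages quoted in summary
#' tables (e.g. a variant funnel stage retaining 258 of 5797 records is
#' reported as 4.45%).
#'
#' @param x Numerator count.
#' @param n Denominator count (> 0).
#' @param digits Decimal places to round the percentage to.
#' @return Numeric percentage, rounded.
#' @examples
#' percentOf(59, 71, digits = 0)
#' @export
percentOf <- function(x, n, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(n), n > 0)
  round(100 * x / n, digits)
}

## 1-based inclusive interval overlap width; 0 when disjoint
overlapWidth <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

assertFraction <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
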