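#' Pool-level editing summary
#'
#' Result container for [quantifyPool()]. Every read of the pool falls into
#' exactly one of three categories: \code{excluded} (no valid flank pair),
#' \code{indel} (window length deviates from the reference) or
#' \code{intact} (window length matches). Frequencies use the number of
#' analyzed reads (indel + intact) as denominator, matching the convention
#' of reporting editing outcomes as a percentage of analyzed reads.
#'
#' @slot ampliconId amplicon the summary refers to.
#' @slot nTotal,nExcluded,nAnalyzed,nIndel,nIntact,nInsertion,nDeletion
#'   read counts; \code{nAnalyzed = nIndel + nIntact},
#'   \code{nTotal = nExcluded + nAnalyzed}.
#' @slot indelFreq,insertionFreq,deletionFreq fractions of analyzed reads
#'   (\code{NaN} when no reads were analyzed).
#' @slot baseFreq numeric matrix, window length x 5 (columns A,C,G,T,N):
#'   per-position base frequencies over intact windows; all-zero rows when
#'   there are no intact reads.
#' @slot programmedEditFreq fraction of analyzed reads that are intact and
#'   carry the donor base at every programmed position (\code{NA} when the
#'   spec defines no donor edits, \code{NaN} when nothing was analyzed).
#' @slot programmedEditFreqIntact same count with the intact reads as
#'   denominator (secondary readout).
#' @slot donorEditFreq named numeric: per donor position, fraction of
#'   analyzed reads intact and carrying the alt base there.
#' @slot indelSizes named integer vector tabulating signed window length
#'   deltas among indel reads.
#' @slot params list echoing \code{maxMismatch}, \code{noRC}, \code{minMeanQ}.
#'
#' @seealso [quantifyPool()], [writeSummary()]
#' @name EditingSummary-class
#' @aliases EditingSummary-class
#' @exportClass EditingSummary
setClass("EditingSummary",
  representation(
    ampliconId = "character",
    nTotal = "integer", nExcluded = "integer", nAnalyzed = "integer",
    nIndel = "integer", nIntact = "integer",
    nInsertion = "integer", nDeletion = "integer",
    indelFreq = "numeric", insertionFreq = "numeric",
    deletionFreq = "numeric",
    baseFreq = "matrix",
    programmedEditFreq = "numeric",
    programmedEditFreqIntact = "numeric",
    donorEditFreq = "numeric",
    indelSizes = "integer",
    params = "list"
  )
)

.validEditingSummary <- function(object) {
  msg <- character()
  if (object@nTotal != object@nExcluded + object@nAnalyzed)
    msg <- c(msg, "nTotal != nExcluded + nAnalyzed")
  if (object@nAnalyzed != object@nIndel + object@nIntact)
    msg <- c(msg, "nAnalyzed != nIndel + nIntact")
  if (object@nIndel != object@nInsertion + object@nDeletion)
    msg <- c(msg, "nIndel != nInsertion + nDeletion")
  bf <- object@baseFreq
  if (ncol(bf) != 5L || !identical(colnames(bf), c("A", "C", "G", "T", "N")))
    msg <- c(msg, "baseFreq must have columns A,C,G,T,N")
  else if (object@nIntact > 0L && nrow(bf) > 0L &&
           any(abs(rowSums(bf) - 1) > 1e-12))
    msg <- c(msg, "baseFreq rows must sum to 1 when intact reads exist")
  pef <- object@programmedEditFreq
  if (length(pef) == 1L && is.finite(pef) && (pef < 0 || pef > 1))
    msg <- c(msg, "programmedEditFreq outside [0, 1]")
  if (length(msg)) msg else TRUE
}
setValidity("EditingSummary", .validEditingSummary)

## ---- accessors -----------------------------------------------------------

#' @rdname EditingSummary-class
#' @param x,object an \code{EditingSummary}.
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))
#' @rdname EditingSummary-class
#' @export
setMethod("nTotal", "EditingSummary", function(x) x@nTotal)

#' @rdname EditingSummary-class
#' @export
setGeneric("nExcluded", function(x) standardGeneric("nExcluded"))
#' @rdname EditingSummary-class
#' @export
setMethod("nExcluded", "EditingSummary", function(x) x@nExcluded)

#' @rdname EditingSummary-class
#' @export
setGeneric("nAnalyzed", function(x) standardGeneric("nAnalyzed"))
#' @rdname EditingSummary-class
#' @export
setMethod("nAnalyzed", "EditingSummary", function(x) x@nAnalyzed)

#' @rdname EditingSummary-class
#' @export
setGeneric("nIndel", function(x) standardGeneric("nIndel"))
#' @rdname EditingSummary-class
#' @export
setMethod("nIndel", "EditingSummary", function(x) x@nIndel)

#' @rdname EditingSummary-class
#' @export
setGeneric("nIntact", function(x) standardGeneric("nIntact"))
#' @rdname EditingSummary-class
#' @export
setMethod("nIntact", "EditingSummary", function(x) x@nIntact)

#' @rdname EditingSummary-class
#' @export
setGeneric("indelFreq", function(x) standardGeneric("indelFreq"))
#' @rdname EditingSummary-class
#' @export
setMethod("indelFreq", "EditingSummary", function(x) x@indelFreq)

#' @rdname EditingSummary-class
#' @export
setGeneric("insertionFreq", function(x) standardGeneric("insertionFreq"))
#' @rdname EditingSummary-class
#' @export
setMethod("insertionFreq", "EditingSummary", function(x) x@insertionFreq)

#' @rdname EditingSummary-class
#' @export
setGeneric("deletionFreq", function(x) standardGeneric("deletionFreq"))
#' @rdname EditingSummary-class
#' @export
setMethod("deletionFreq", "EditingSummary", function(x) x@deletionFreq)

#' @rdname EditingSummary-class
#' @export
setGeneric("baseFreq", function(x) standardGeneric("baseFreq"))
#' @rdname EditingSummary-class
#' @export
setMethod("baseFreq", "EditingSummary", function(x) x@baseFreq)

#' @rdname EditingSummary-class
#' @export
setGeneric("programmedEditFreq", function(x) standardGeneric("programmedEditFreq"))
#' @rdname EditingSummary-class
#' @export
setMethod("programmedEditFreq", "EditingSummary",
          function(x) x@programmedEditFreq)

#' @rdname EditingSummary-class
#' @export
setGeneric("donorEditFreq", function(x) standardGeneric("donorEditFreq"))
#' @rdname EditingSummary-class
#' @export
setMethod("donorEditFreq", "EditingSummary", function(x) x@donorEditFreq)

#' @rdname EditingSummary-class
#' @export
setGeneric("indelSizes", function(x) standardGeneric("indelSizes"))
#' @rdname EditingSummary-class
#' @export
setMethod("indelSizes", "EditingSummary", function(x) x@indelSizes)

.pct <- function(x) {
  if (!length(x) || !is.finite(x)) "NA" else sprintf("%.2f%%", 100 * x)
}

setMethod("show", "EditingSummary", function(object) {
  cat("EditingSummary for amplicon '", object@ampliconId, "'\n", sep = "")
  cat(sprintf("  reads: %d total = %d excluded + %d analyzed (%d indel, %d intact)\n",
              object@nTotal, object@nExcluded, object@nAnalyzed,
              object@nIndel, object@nIntact))
  cat("  indel frequency:          ", .pct(object@indelFreq),
      " (ins ", .pct(object@insertionFreq),
      ", del ", .pct(object@deletionFreq), ")\n", sep = "")
  cat("  programmed-edit frequency:", .pct(object@programmedEditFreq),
      "of analyzed reads\n")
})
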