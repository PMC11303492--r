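#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern vmatchPattern countPattern neditStartingAt consensusMatrix
#'   subseq PhredQuality QualityScaledDNAStringSet
#'   readDNAStringSet writeQualityScaledXStringSet quality
#' @importFrom BiocGenerics start end width
#' @importFrom S4Vectors isConstant
#' @importClassesFrom Biostrings DNAString DNAStringSet
#'   QualityScaledDNAStringSet
NULL

#' Amplicon editing-window specification
#'
#' An \code{AmpliconSpec} describes a PCR amplicon of an edited locus: the
#' full reference amplicon sequence, two short flank anchors (10 bp by
#' convention) that delimit the editing window where CRISPR-induced indels
#' and base changes are expected, the reference sequence of that window, and
#' the programmed donor edit(s) -- the substitution(s) a homology-directed
#' repair template installs (for the TIE2 L914F model system, a single C>T).
#'
#' @slot ampliconId single character, identifier for the locus/amplicon.
#' @slot ampliconSeq \code{\link[Biostrings]{DNAString}}, uppercase ACGT.
#' @slot leftFlank,rightFlank \code{DNAString} anchors; each must occur
#'   exactly once in \code{ampliconSeq}, left before right, non-overlapping.
#' @slot windowRef \code{DNAString}; the amplicon subsequence strictly
#'   between the flanks (derived by the constructor).
#' @slot donorEdits \code{data.frame} with columns \code{pos} (1-based
#'   position within the window), \code{ref} and \code{alt} (single bases);
#'   zero rows mean no programmed edit is being tracked.
#'
#' @seealso [AmpliconSpec()] for construction, [quantifyPool()] for use.
#' @name AmpliconSpec-class
#' @aliases AmpliconSpec-class
#' @exportClass AmpliconSpec
setClass("AmpliconSpec",
  representation(
    ampliconId = "character",
    ampliconSeq = "DNAString",
    leftFlank = "DNAString",
    rightFlank = "DNAString",
    windowRef = "DNAString",
    donorEdits = "data.frame"
  )
)

.validAmpliconSpec <- function(object) {
  msg <- character()
  amp <- object@ampliconSeq
  lf <- object@leftFlank
  rf <- object@rightFlank
  if (length(object@ampliconId) != 1L || is.na(object@ampliconId) ||
      !nzchar(object@ampliconId))
    msg <- c(msg, "'ampliconId' must be a single non-empty string")
  if (length(amp) == 0L)
    msg <- c(msg, "'ampliconSeq' must be non-empty")
  for (nm in c("ampliconSeq", "leftFlank", "rightFlank")) {
    s <- as.character(slot(object, nm))
    if (grepl("[^ACGT]", s))
      msg <- c(msg, sprintf("'%s' must contain only uppercase A/C/G/T", nm))
  }
  if (length(lf) == 0L || length(rf) == 0L) {
    msg <- c(msg, "flanks must be non-empty")
    return(if (length(msg)) msg else TRUE)
  }
  nl <- countPattern(lf, amp, fixed = TRUE)
  nr <- countPattern(rf, amp, fixed = TRUE)
  if (nl != 1L)
    msg <- c(msg, sprintf("left flank occurs %d times in amplicon (need exactly 1)", nl))
  if (nr != 1L)
    msg <- c(msg, sprintf("right flank occurs %d times in amplicon (need exactly 1)", nr))
  if (nl == 1L && nr == 1L) {
    lm <- matchPattern(lf, amp, fixed = TRUE)
    rm_ <- matchPattern(rf, amp, fixed = TRUE)
    if (end(lm) >= start(rm_))
      msg <- c(msg, "left flank must end strictly before right flank starts")
    else {
      wref <- as.character(subseq(amp, end(lm) + 1L, start(rm_) - 1L))
      if (!identical(wref, as.character(object@windowRef)))
        msg <- c(msg, "'windowRef' does not equal the amplicon subsequence between the flanks")
    }
  }
  de <- object@donorEdits
  if (!all(c("pos", "ref", "alt") %in% names(de)))
    msg <- c(msg, "'donorEdits' needs columns pos, ref, alt")
  else if (nrow(de) > 0L) {
    wref <- as.character(object@windowRef)
    if (any(de$pos < 1L | de$pos > nchar(wref)))
      msg <- c(msg, "donor edit positions must lie within the window")
    else {
      refAt <- substring(wref, de$pos, de$pos)
      if (any(refAt != de$ref))
        msg <- c(msg, "donor edit 'ref' base does not match the window reference")
    }
    if (any(!de$ref %in% c("A", "C", "G", "T")) ||
        any(!de$alt %in% c("A", "C", "G", "T")))
      msg <- c(msg, "donor edit bases must be A/C/G/T")
    if (any(de$ref == de$alt))
      msg <- c(msg, "donor edit 'ref' and 'alt' must differ")
    if (anyDuplicated(de$pos))
      msg <- c(msg, "donor edit positions must be unique")
  }
  if (length(msg)) msg else TRUE
}
setValidity("AmpliconSpec", .validAmpliconSpec)

.asDNAString <- function(x, what) {
  if (is(x, "DNAString")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(DNAString(toupper(x)))
  stop("'", what, "' must be a single character string or DNAString",
       call. = FALSE)
}

#' Construct an AmpliconSpec
#'
#' The window reference sequence is derived from the amplicon and the two
#' flank anchors; validity (unique flank occurrence, ordering, donor-edit
#' consistency) is checked on construction.
#'
#' @param ampliconId identifier for the amplicon.
#' @param ampliconSeq reference amplicon, character or \code{DNAString}.
#' @param leftFlank,rightFlank flank anchor sequences (10 bp by convention,
#'   any positive length accepted).
#' @param donorEdits \code{data.frame(pos, ref, alt)} with 1-based window
#'   positions, or a character vector in \code{"pos:REF>ALT"} form.
#' @return An [AmpliconSpec-class] object.
#' @examples
#' spec <- AmpliconSpec("toy",
#'   ampliconSeq = "GGGTTACCTGGAGTAACGTACGTACGTACGTGTCATGGAACCCC",
#'   leftFlank = "ACCTGGAGTA", rightFlank = "GTCATGGAAC",
#'   donorEdits = "3:G>T")
#' windowRef(spec)
#' @export
AmpliconSpec <- function(ampliconId, ampliconSeq, leftFlank, rightFlank,
                         donorEdits = data.frame(pos = integer(),
                                                 ref = character(),
                                                 alt = character())) {
  amp <- .asDNAString(ampliconSeq, "ampliconSeq")
  lf <- .asDNAString(leftFlank, "leftFlank")
  rf <- .asDNAString(rightFlank, "rightFlank")
  if (is.character(donorEdits))
    donorEdits <- parseDonorEdits(donorEdits)
  donorEdits <- as.data.frame(donorEdits, stringsAsFactors = FALSE)
  if (nrow(donorEdits))
    donorEdits$pos <- as.integer(donorEdits$pos)
  lm <- matchPattern(lf, amp, fixed = TRUE)
  rm_ <- matchPattern(rf, amp, fixed = TRUE)
  if (length(lm) != 1L || length(rm_) != 1L || end(lm)[1L] >= start(rm_)[1L])
    wref <- DNAString("")        # validity reports the precise failure
  else
    wref <- DNAString(as.character(subseq(amp, end(lm)[1L] + 1L,
                                          start(rm_)[1L] - 1L)))
  new("AmpliconSpec", ampliconId = as.character(ampliconId),
      ampliconSeq = amp, leftFlank = lf, rightFlank = rf,
      windowRef = wref, donorEdits = donorEdits)
}

#' Parse donor edits from "pos:REF>ALT" strings
#'
#' @param x character vector, e.g. \code{c("8:C>T")}; positions are 1-based
#'   within the editing window.
#' @return \code{data.frame(pos, ref, alt)}.
#' @export
parseDonorEdits <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+):([ACGT])>([ACGT])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed donor edit spec (want 'pos:REF>ALT'): ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  data.frame(pos = as.integer(vapply(m, `[`, "", 2L)),
             ref = vapply(m, `[`, "", 3L),
             alt = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

## ---- accessors -----------------------------------------------------------

#' @rdname AmpliconSpec-class
#' @param x,object an \code{AmpliconSpec}.
#' @export
setGeneric("ampliconId", function(x) standardGeneric("ampliconId"))
#' @rdname AmpliconSpec-class
#' @export
setMethod("ampliconId", "AmpliconSpec", function(x) x@ampliconId)

#' @rdname AmpliconSpec-class
#' @export
setGeneric("ampliconSeq", function(x) standardGeneric("ampliconSeq"))
#' @rdname AmpliconSpec-class
#' @export
setMethod("ampliconSeq", "AmpliconSpec", function(x) x@ampliconSeq)

#' @rdname AmpliconSpec-class
#' @export
setGeneric("leftFlank", function(x) standardGeneric("leftFlank"))
#' @rdname AmpliconSpec-class
#' @export
setMethod("leftFlank", "AmpliconSpec", function(x) x@leftFlank)

#' @rdname AmpliconSpec-class
#' @export
setGeneric("rightFlank", function(x) standardGeneric("rightFlank"))
#' @rdname AmpliconSpec-class
#' @export
setMethod("rightFlank", "AmpliconSpec", function(x) x@rightFlank)

#' @rdname AmpliconSpec-class
#' @export
setGeneric("windowRef", function(x) standardGeneric("windowRef"))
#' @rdname AmpliconSpec-class
#' @export
setMethod("windowRef", "AmpliconSpec", function(x) x@windowRef)

#' @rdname AmpliconSpec-class
#' @export
setGeneric("donorEdits", function(x) standardGeneric("donorEdits"))
#' @rdname AmpliconSpec-class
#' @export
setMethod("donorEdits", "AmpliconSpec", function(x) x@donorEdits)

#' Window sequence with the programmed donor edit(s) applied
#'
#' @param x an \code{AmpliconSpec} with at least one donor edit.
#' @return single character string: \code{windowRef} with every donor
#'   \code{alt} base substituted in.
#' @export
setGeneric("hdrWindow", function(x) standardGeneric("hdrWindow"))
#' @rdname hdrWindow
#' @export
setMethod("hdrWindow", "AmpliconSpec", function(x) {
  de <- donorEdits(x)
  if (nrow(de) == 0L)
    stop("no donor edits defined for this amplicon", call. = FALSE)
  w <- strsplit(as.character(windowRef(x)), "")[[1L]]
  w[de$pos] <- de$alt
  paste(w, collapse = "")
})

setMethod("show", "AmpliconSpec", function(object) {
  de <- donorEdits(object)
  cat("AmpliconSpec '", ampliconId(object), "'\n", sep = "")
  cat("  amplicon: ", length(object@ampliconSeq), " bp\n", sep = "")
  cat("  flanks:   ", as.character(object@leftFlank), " | ",
      as.character(object@rightFlank), "\n", sep = "")
  cat("  window:   ", as.character(object@windowRef), " (",
      length(object@windowRef), " bp)\n", sep = "")
  if (nrow(de))
    cat("  donor edits: ",
        paste(sprintf("%d:%s>%s", de$pos, de$ref, de$alt), collapse = ", "),
        "\n", sep = "")
  else cat("  donor edits: none\n")
})
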