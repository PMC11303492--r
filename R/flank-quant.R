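## Flank-anchored read classification.
##
## A read is searched for one placement of the left and right flank anchors
## (per-flank Hamming distance <= maxMismatch, left strictly before right,
## non-overlapping). Among all valid placements the pair with the smallest
## total mismatch count wins; ties go to the leftmost left placement, then
## the leftmost right placement. The forward read is searched first; the
## reverse complement is used only when it has a strictly smaller total
## mismatch count (or when forward has no valid pair). An N in the read
## always counts as a mismatch.

## per-candidate Hamming distance to the flank, vectorized over candidates
.hammingToPattern <- function(substrs, patternChars) {
  mm <- integer(length(substrs))
  for (j in seq_along(patternChars))
    mm <- mm + (substr(substrs, j, j) != patternChars[j])
  mm
}

## all placements of `flank` in each sequence with <= maxMismatch mismatches;
## returns parallel vectors (read index, 1-based start, mismatch count)
.candidateTable <- function(seqSet, sChar, flank, maxMismatch) {
  w <- length(flank)
  hits <- Biostrings::startIndex(
    vmatchPattern(flank, seqSet, max.mismatch = maxMismatch, fixed = TRUE))
  n <- lengths(hits)
  i <- rep.int(seq_along(hits), n)
  start <- as.integer(unlist(hits, use.names = FALSE))
  if (!length(start))
    return(list(i = integer(), start = integer(), mm = integer()))
  ok <- start >= 1L & start + w - 1L <= nchar(sChar)[i]
  i <- i[ok]; start <- start[ok]
  mm <- .hammingToPattern(substring(sChar[i], start, start + w - 1L),
                          strsplit(as.character(flank), "")[[1L]])
  ok <- mm <= maxMismatch
  list(i = i[ok], start = start[ok], mm = as.integer(mm[ok]))
}

## best valid (left, right) placement among explicit candidates, or NULL
.selectPairOne <- function(lStarts, lMM, rStarts, rMM, lWidth) {
  if (!length(lStarts) || !length(rStarts)) return(NULL)
  li <- rep(seq_along(lStarts), times = length(rStarts))
  ri <- rep(seq_along(rStarts), each = length(lStarts))
  ok <- lStarts[li] + lWidth <= rStarts[ri]
  if (!any(ok)) return(NULL)
  li <- li[ok]; ri <- ri[ok]
  tot <- lMM[li] + rMM[ri]
  best <- order(tot, lStarts[li], rStarts[ri])[1L]
  list(leftStart = lStarts[li[best]], rightStart = rStarts[ri[best]],
       leftMM = lMM[li[best]], rightMM = rMM[ri[best]],
       total = tot[best])
}

## best pair per sequence for a whole set; data.frame with found flag
.bestPairsForSet <- function(seqSet, sChar, spec, maxMismatch) {
  n <- length(seqSet)
  lW <- length(leftFlank(spec))
  out <- data.frame(found = logical(n),
                    leftStart = rep(NA_integer_, n),
                    rightStart = rep(NA_integer_, n),
                    leftMM = rep(NA_integer_, n),
                    rightMM = rep(NA_integer_, n),
                    total = rep(NA_integer_, n))
  if (n == 0L) return(out)
  cl <- .candidateTable(seqSet, sChar, leftFlank(spec), maxMismatch)
  cr <- .candidateTable(seqSet, sChar, rightFlank(spec), maxMismatch)
  nl <- tabulate(cl$i, n)
  nr <- tabulate(cr$i, n)
  ## fast path: single candidate on each side
  single <- which(nl == 1L & nr == 1L)
  if (length(single)) {
    posL <- match(single, cl$i)   # unique hit per read
    posR <- match(single, cr$i)
    valid <- cl$start[posL] + lW <= cr$start[posR]
    sv <- single[valid]
    out$found[sv] <- TRUE
    out$leftStart[sv] <- cl$start[posL][valid]
    out$rightStart[sv] <- cr$start[posR][valid]
    out$leftMM[sv] <- cl$mm[posL][valid]
    out$rightMM[sv] <- cr$mm[posR][valid]
    out$total[sv] <- out$leftMM[sv] + out$rightMM[sv]
  }
  multi <- which(nl > 0L & nr > 0L & (nl > 1L | nr > 1L))
  if (length(multi)) {
    f <- factor(cl$i, levels = multi)
    lsS <- split(cl$start, f); lmS <- split(cl$mm, f)
    f <- factor(cr$i, levels = multi)
    rsS <- split(cr$start, f); rmS <- split(cr$mm, f)
    for (k in seq_along(multi)) {
      b <- .selectPairOne(lsS[[k]], lmS[[k]], rsS[[k]], rmS[[k]], lW)
      if (is.null(b)) next
      j <- multi[k]
      out$found[j] <- TRUE
      out$leftStart[j] <- b$leftStart; out$rightStart[j] <- b$rightStart
      out$leftMM[j] <- b$leftMM; out$rightMM[j] <- b$rightMM
      out$total[j] <- b$total
    }
  }
  out
}

.asReadSet <- function(reads) {
  if (is(reads, "QualityScaledDNAStringSet")) as(reads, "DNAStringSet")
  else if (is(reads, "DNAStringSet")) reads
  else if (is(reads, "DNAString")) DNAStringSet(reads)
  else if (is.character(reads)) DNAStringSet(toupper(reads))
  else stop("'reads' must be a character vector, DNAString or DNAStringSet",
            call. = FALSE)
}

#' Classify every read of a pool against the editing window
#'
#' Locates the two flank anchors in each read (forward, then reverse
#' complement; see Details), extracts the intervening window, and assigns
#' one of three categories: \code{"excluded"} (no valid flank pair),
#' \code{"indel"} (window length deviates from the reference; the signed
#' deviation is reported) or \code{"intact"} (window length matches).
#'
#' @details All placements of each flank with at most \code{maxMismatch}
#' mismatches (Hamming distance; an \code{N} counts as a mismatch) are
#' enumerated; among valid left-before-right, non-overlapping pairs the one
#' with the smallest total mismatch count wins, ties resolved to the
#' leftmost left start then the leftmost right start. The reverse
#' complement of the read is used only when it yields a valid pair and the
#' forward read does not, or when its best total mismatch count is strictly
#' smaller. Coordinates are 1-based and refer to the oriented read (the
#' reverse-complemented sequence when \code{orientation} is
#' \code{"reverse_complement"}).
#'
#' @param reads character vector, \code{DNAStringSet} or
#'   \code{QualityScaledDNAStringSet} of amplicon reads.
#' @param spec an [AmpliconSpec-class].
#' @param maxMismatch maximum mismatches allowed in each flank
#'   (default 1, the conventional allowance for 10 bp anchors).
#' @param noRC if \code{TRUE}, do not search the reverse complement.
#' @return \code{data.frame} with one row per read: \code{readId},
#'   \code{category}, \code{lengthDelta} (signed, indel reads only),
#'   \code{observedWindow} (intact and indel reads), \code{orientation},
#'   \code{leftStart}, \code{rightStart}, \code{leftMismatches},
#'   \code{rightMismatches}.
#' @seealso [findFlanks()] for a single read, [quantifyPool()] for the
#'   pool-level summary.
#' @export
classifyReads <- function(reads, spec, maxMismatch = 1L, noRC = FALSE) {
  stopifnot(is(spec, "AmpliconSpec"))
  if (maxMismatch < 0L) stop("'maxMismatch' must be >= 0", call. = FALSE)
  seqSet <- .asReadSet(reads)
  n <- length(seqSet)
  ids <- names(seqSet)
  if (is.null(ids)) ids <- sprintf("read%d", seq_len(n))
  if (n && any(width(seqSet) == 0L))
    stop("invalid input: empty read sequence", call. = FALSE)
  sChar <- as.character(seqSet)

  fwd <- .bestPairsForSet(seqSet, sChar, spec, maxMismatch)
  orientation <- rep("forward", n)
  oriented <- sChar
  best <- fwd
  if (!noRC && n) {
    ## reverse complement can only win with strictly fewer total mismatches
    needRC <- which(!fwd$found | fwd$total > 0L)
    if (length(needRC)) {
      rcSet <- reverseComplement(seqSet[needRC])
      rcChar <- as.character(rcSet)
      rc <- .bestPairsForSet(rcSet, rcChar, spec, maxMismatch)
      take <- rc$found & (!fwd$found[needRC] | rc$total < fwd$total[needRC])
      idx <- needRC[take]
      best[idx, ] <- rc[take, ]
      orientation[idx] <- "reverse_complement"
      oriented[idx] <- rcChar[take]
    }
  }

  lW <- length(leftFlank(spec))
  refLen <- length(windowRef(spec))
  category <- rep("excluded", n)
  lengthDelta <- rep(NA_integer_, n)
  observedWindow <- rep(NA_character_, n)
  f <- which(best$found)
  if (length(f)) {
    winStart <- best$leftStart[f] + lW
    winEnd <- best$rightStart[f] - 1L
    obs <- substring(oriented[f], winStart, winEnd)  # "" for winEnd < winStart
    delta <- nchar(obs) - refLen
    category[f] <- ifelse(delta == 0L, "intact", "indel")
    indelIdx <- f[delta != 0L]
    lengthDelta[indelIdx] <- as.integer(delta[delta != 0L])
    observedWindow[f] <- obs
  }
  orientation[category == "excluded"] <- NA_character_
  data.frame(readId = ids, category = category, lengthDelta = lengthDelta,
             observedWindow = observedWindow, orientation = orientation,
             leftStart = best$leftStart, rightStart = best$rightStart,
             leftMismatches = best$leftMM, rightMismatches = best$rightMM,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Locate the flank anchors in a single read
#'
#' @inheritParams classifyReads
#' @param read a single read (character, \code{DNAString}).
#' @return \code{NULL} when no valid flank pair exists in either
#'   orientation; otherwise a list with \code{leftStart}, \code{rightStart}
#'   (1-based starts in the oriented read), \code{leftMismatches},
#'   \code{rightMismatches} and \code{orientation} (\code{"forward"} or
#'   \code{"reverse_complement"}).
#' @examples
#' spec <- AmpliconSpec("toy",
#'   "GGGTTACCTGGAGTAACGTACGTACGTACGTGTCATGGAACCCC",
#'   "ACCTGGAGTA", "GTCATGGAAC")
#' findFlanks(paste0("ACCTGGAGTA", "ACGTACGTACGTACGT", "GTCATGGAAC"), spec)
#' @export
findFlanks <- function(read, spec, maxMismatch = 1L, noRC = FALSE) {
  if (is.character(read) && length(read) != 1L)
    stop("'read' must be a single sequence", call. = FALSE)
  cls <- classifyReads(read, spec, maxMismatch = maxMismatch, noRC = noRC)
  if (cls$category[1L] == "excluded") return(NULL)
  list(leftStart = cls$leftStart[1L], rightStart = cls$rightStart[1L],
       leftMismatches = cls$leftMismatches[1L],
       rightMismatches = cls$rightMismatches[1L],
       orientation = cls$orientation[1L])
}

#' Classify a single read
#'
#' @inheritParams findFlanks
#' @return list with \code{category} (\code{"excluded"}, \code{"indel"} or
#'   \code{"intact"}), \code{lengthDelta} (signed window-length deviation,
#'   \code{NA} unless an indel), \code{observedWindow} (\code{NA} when
#'   excluded) and \code{flankMatch} (as [findFlanks()], or \code{NULL}).
#' @export
classifyRead <- function(read, spec, maxMismatch = 1L, noRC = FALSE) {
  cls <- classifyReads(read, spec, maxMismatch = maxMismatch, noRC = noRC)
  fm <- if (cls$category[1L] == "excluded") NULL else
    list(leftStart = cls$leftStart[1L], rightStart = cls$rightStart[1L],
         leftMismatches = cls$leftMismatches[1L],
         rightMismatches = cls$rightMismatches[1L],
         orientation = cls$orientation[1L])
  list(category = cls$category[1L], lengthDelta = cls$lengthDelta[1L],
       observedWindow = cls$observedWindow[1L], flankMatch = fm)
}

#' Per-position base frequencies over intact windows
#'
#' Row \code{i} is the empirical distribution of A, C, G, T and N at window
#' position \code{i} across the supplied windows (each the same length as
#' the reference window). Bases other than A/C/G/T are tallied as N. These
#' per-position frequencies are the base-edit readout for reads whose
#' window length matches the reference.
#'
#' @param windows character vector or \code{DNAStringSet} of observed
#'   intact windows.
#' @param windowRef reference window sequence (character or
#'   \code{DNAString}); only its length is used.
#' @return numeric matrix, \code{nchar(windowRef)} rows by 5 columns
#'   (A, C, G, T, N). Rows sum to 1; the all-zero matrix when no windows
#'   are supplied.
#' @examples
#' baseFrequencyMatrix(c("ACG", "ACG", "ACT"), "ACG")
#' @export
baseFrequencyMatrix <- function(windows, windowRef) {
  refLen <- if (is(windowRef, "DNAString")) length(windowRef)
            else nchar(as.character(windowRef))
  if (is(windows, "DNAStringSet")) windows <- as.character(windows)
  windows <- as.character(windows)
  bases <- c("A", "C", "G", "T", "N")
  out <- matrix(0, nrow = refLen, ncol = 5L,
                dimnames = list(NULL, bases))
  if (length(windows) == 0L || refLen == 0L) {
    if (length(windows) && any(nchar(windows) != refLen))
      stop("all windows must have the reference window length",
           call. = FALSE)
    return(out)
  }
  if (any(nchar(windows) != refLen))
    stop("all windows must have the reference window length", call. = FALSE)
  cm <- consensusMatrix(DNAStringSet(windows))   # letters x position counts
  for (b in c("A", "C", "G", "T"))
    if (b %in% rownames(cm)) out[, b] <- cm[b, ]
  other <- setdiff(rownames(cm), c("A", "C", "G", "T"))
  if (length(other))
    out[, "N"] <- colSums(cm[other, , drop = FALSE])
  out / length(windows)
}

#' Programmed-edit (knock-in) frequency
#'
#' The fraction of analyzed reads that have an intact-length window carrying
#' the donor \code{alt} base at \emph{every} programmed position — the
#' read-level estimate of precise knock-in efficiency. Per-position donor
#' base frequencies are reported alongside, as is the same count over the
#' intact reads only (secondary denominator).
#'
#' @param intactWindows character vector of observed windows from intact
#'   reads (all of reference length).
#' @param spec an [AmpliconSpec-class] with at least one donor edit.
#' @param nAnalyzed number of analyzed reads (indel + intact), the
#'   denominator.
#' @return list with \code{freq} (per analyzed read), \code{freqIntact}
#'   (per intact read) and \code{perPosition} (named numeric, per donor
#'   position, per analyzed read). All \code{NaN} when \code{nAnalyzed}
#'   is 0.
#' @export
programmedEditFrequency <- function(intactWindows, spec, nAnalyzed) {
  de <- donorEdits(spec)
  if (nrow(de) == 0L)
    stop("configuration error: amplicon spec defines no donor edits",
         call. = FALSE)
  refLen <- length(windowRef(spec))
  if (length(intactWindows) && any(nchar(intactWindows) != refLen))
    stop("intact windows must have the reference window length",
         call. = FALSE)
  hasAlt <- matrix(FALSE, nrow = length(intactWindows), ncol = nrow(de))
  for (k in seq_len(nrow(de)))
    hasAlt[, k] <- substr(intactWindows, de$pos[k], de$pos[k]) == de$alt[k]
  nAll <- sum(rowSums(hasAlt) == nrow(de))
  perPos <- colSums(hasAlt) / nAnalyzed
  names(perPos) <- sprintf("%d:%s>%s", de$pos, de$ref, de$alt)
  list(freq = nAll / nAnalyzed,
       freqIntact = nAll / length(intactWindows),
       perPosition = perPos)
}

#' Quantify editing outcomes in a read pool
#'
#' Runs [classifyReads()] on the pool and summarises: counts per category,
#' indel/insertion/deletion frequencies (denominator: analyzed reads),
#' per-position base frequencies over intact windows, and — when the spec
#' defines donor edits — the programmed-edit frequency.
#'
#' @inheritParams classifyReads
#' @param minMeanQ optional minimum mean Phred quality; reads below it are
#'   excluded before flank search (requires quality-scaled input). Off by
#'   default: the reference procedure applies no quality filter.
#' @return An [EditingSummary-class].
#' @examples
#' spec <- AmpliconSpec("toy",
#'   "GGGTTACCTGGAGTAACGTACGTACGTACGTGTCATGGAACCCC",
#'   "ACCTGGAGTA", "GTCATGGAAC", donorEdits = "3:G>T")
#' reads <- c(paste0("ACCTGGAGTA", "ACTTACGTACGTACGT", "GTCATGGAAC"),
#'            paste0("ACCTGGAGTA", "ACGTACGTACGTACGT", "GTCATGGAAC"))
#' quantifyPool(reads, spec)
#' @export
quantifyPool <- function(reads, spec, maxMismatch = 1L, noRC = FALSE,
                         minMeanQ = NULL) {
  stopifnot(is(spec, "AmpliconSpec"))
  nQualityFail <- 0L
  if (!is.null(minMeanQ)) {
    if (!is(reads, "QualityScaledDNAStringSet"))
      stop("'minMeanQ' requires quality-scaled reads (see readFastq())",
           call. = FALSE)
    q <- as(quality(reads), "IntegerList")
    meanQ <- vapply(q, function(v) mean(as.numeric(v)), numeric(1))
    keep <- meanQ >= minMeanQ
    nQualityFail <- sum(!keep)
    reads <- reads[keep]
  }
  cls <- classifyReads(reads, spec, maxMismatch = maxMismatch, noRC = noRC)
  nTotal <- nrow(cls) + nQualityFail
  nIntact <- sum(cls$category == "intact")
  nIndel <- sum(cls$category == "indel")
  nAnalyzed <- nIntact + nIndel
  nExcluded <- nTotal - nAnalyzed
  deltas <- cls$lengthDelta[cls$category == "indel"]
  nInsertion <- sum(deltas > 0L)
  nDeletion <- sum(deltas < 0L)
  if (nAnalyzed == 0L) {
    if (nTotal > 0L)
      warning("no analyzed reads; frequencies are undefined (NaN)",
              call. = FALSE)
    indelFreq <- insertionFreq <- deletionFreq <- NaN
  } else {
    indelFreq <- nIndel / nAnalyzed
    insertionFreq <- nInsertion / nAnalyzed
    deletionFreq <- nDeletion / nAnalyzed
  }
  intactWindows <- cls$observedWindow[cls$category == "intact"]
  bf <- baseFrequencyMatrix(intactWindows, windowRef(spec))
  de <- donorEdits(spec)
  if (nrow(de) == 0L) {
    pef <- NA_real_; pefIntact <- NA_real_; perPos <- numeric()
  } else if (nAnalyzed == 0L) {
    pef <- NaN; pefIntact <- NaN
    perPos <- rep(NaN, nrow(de))
    names(perPos) <- sprintf("%d:%s>%s", de$pos, de$ref, de$alt)
  } else {
    p <- programmedEditFrequency(intactWindows, spec, nAnalyzed)
    pef <- p$freq; pefIntact <- p$freqIntact; perPos <- p$perPosition
  }
  sizes <- integer()
  if (length(deltas)) {
    tb <- table(deltas)
    sizes <- as.integer(tb)
    names(sizes) <- names(tb)
  }
  new("EditingSummary", ampliconId = ampliconId(spec),
      nTotal = as.integer(nTotal), nExcluded = as.integer(nExcluded),
      nAnalyzed = as.integer(nAnalyzed), nIndel = as.integer(nIndel),
      nIntact = as.integer(nIntact), nInsertion = as.integer(nInsertion),
      nDeletion = as.integer(nDeletion),
      indelFreq = indelFreq, insertionFreq = insertionFreq,
      deletionFreq = deletionFreq, baseFreq = bf,
      programmedEditFreq = pef, programmedEditFreqIntact = pefIntact,
      donorEditFreq = perPos, indelSizes = sizes,
      params = list(maxMismatch = as.integer(maxMismatch), noRC = noRC,
                    minMeanQ = minMeanQ))
}
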