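## Seeded simulator for amplicon read pools with known editing-outcome
## composition. Each read is the reference amplicon with the editing window
## replaced by its allele's window sequence, then perturbed by i.i.d.
## per-base substitution errors. Sequencing indel errors are not modelled
## (a length change is, by construction of the classifier, a biological
## call); an optional indel-error rate exists to stress-test that
## assumption.

#' Simulated pool specification
#'
#' Truth model for [simulatePool()]: a mixture of allele classes (wild-type,
#' precise HDR edit, indel alleles), each with a window sequence and a
#' proportion, read out as full-length amplicon reads with a per-base
#' substitution error rate. A fixed seed makes the output byte-identical
#' across runs.
#'
#' @slot amplicon the [AmpliconSpec-class] being sequenced.
#' @slot alleles \code{data.frame(label, kind, windowSeq, proportion)};
#'   \code{kind} is \code{"WT"}, \code{"HDR"} or \code{"INDEL"};
#'   proportions sum to 1 (tolerance 1e-9). An HDR allele's window differs
#'   from the reference exactly at the donor positions; an INDEL allele's
#'   window length differs from the reference.
#' @slot nReads number of reads to draw.
#' @slot errorRate per-base substitution probability in [0, 1).
#' @slot indelErrorRate per-base probability of a 1 bp sequencing
#'   insertion/deletion error (0 by default; see Details in
#'   [simulatePool()]).
#' @slot readLength read length; \code{NA} (default) means full-amplicon
#'   reads, as for short PCR products.
#' @slot seed integer RNG seed.
#' @name PoolSpec-class
#' @aliases PoolSpec-class
#' @exportClass PoolSpec
setClass("PoolSpec",
  representation(
    amplicon = "AmpliconSpec",
    alleles = "data.frame",
    nReads = "integer",
    errorRate = "numeric",
    indelErrorRate = "numeric",
    readLength = "integer",
    seed = "integer"
  )
)

.validPoolSpec <- function(object) {
  msg <- character()
  al <- object@alleles
  need <- c("label", "kind", "windowSeq", "proportion")
  if (!all(need %in% names(al)))
    return("'alleles' needs columns label, kind, windowSeq, proportion")
  if (nrow(al) == 0L) msg <- c(msg, "at least one allele is required")
  if (abs(sum(al$proportion) - 1) > 1e-9)
    msg <- c(msg, "allele proportions must sum to 1")
  if (any(al$proportion < 0))
    msg <- c(msg, "allele proportions must be non-negative")
  if (anyDuplicated(al$label))
    msg <- c(msg, "allele labels must be unique")
  if (!all(al$kind %in% c("WT", "HDR", "INDEL")))
    msg <- c(msg, "allele kind must be WT, HDR or INDEL")
  wref <- as.character(windowRef(object@amplicon))
  de <- donorEdits(object@amplicon)
  for (i in seq_len(nrow(al))) {
    w <- al$windowSeq[i]
    if (grepl("[^ACGT]", w)) {
      msg <- c(msg, sprintf("allele '%s': window must be A/C/G/T", al$label[i]))
      next
    }
    if (al$kind[i] == "WT" && w != wref)
      msg <- c(msg, sprintf("allele '%s': WT window must equal the reference window", al$label[i]))
    if (al$kind[i] == "INDEL" && nchar(w) == nchar(wref))
      msg <- c(msg, sprintf("allele '%s': INDEL window must differ in length from the reference", al$label[i]))
    if (al$kind[i] == "HDR") {
      if (nchar(w) != nchar(wref))
        msg <- c(msg, sprintf("allele '%s': HDR window must match the reference length", al$label[i]))
      else if (nrow(de)) {
        diffPos <- which(strsplit(w, "")[[1L]] != strsplit(wref, "")[[1L]])
        if (!setequal(diffPos, de$pos) ||
            !all(substring(w, de$pos, de$pos) == de$alt))
          msg <- c(msg, sprintf("allele '%s': HDR window must differ from the reference exactly at the donor positions", al$label[i]))
      }
    }
  }
  if (object@nReads <= 0L) msg <- c(msg, "nReads must be > 0")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  if (object@indelErrorRate < 0 || object@indelErrorRate >= 1)
    msg <- c(msg, "indelErrorRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
}
setValidity("PoolSpec", .validPoolSpec)

#' @rdname PoolSpec-class
#' @param amplicon an [AmpliconSpec-class].
#' @param alleles \code{data.frame} as produced by [alleleWT()],
#'   [alleleHDR()], [alleleIndel()] (rows may simply be concatenated with
#'   \code{rbind}).
#' @param nReads number of reads.
#' @param errorRate per-base substitution probability (default 0).
#' @param indelErrorRate per-base 1 bp indel error probability (default 0).
#' @param readLength \code{NA} for full-amplicon reads, otherwise a length
#'   long enough to span both flanks for every allele.
#' @param seed RNG seed.
#' @export
PoolSpec <- function(amplicon, alleles, nReads, errorRate = 0,
                     indelErrorRate = 0, readLength = NA_integer_,
                     seed = 1L) {
  new("PoolSpec", amplicon = amplicon,
      alleles = as.data.frame(alleles, stringsAsFactors = FALSE),
      nReads = as.integer(nReads), errorRate = as.numeric(errorRate),
      indelErrorRate = as.numeric(indelErrorRate),
      readLength = as.integer(readLength), seed = as.integer(seed))
}

setMethod("show", "PoolSpec", function(object) {
  cat("PoolSpec:", object@nReads, "reads from amplicon '",
      ampliconId(object@amplicon), "', error rate ", object@errorRate,
      ", seed ", object@seed, "\n")
  al <- object@alleles
  for (i in seq_len(nrow(al)))
    cat(sprintf("  %-12s %-5s p=%-8g window %d bp\n", al$label[i],
                al$kind[i], al$proportion[i], nchar(al$windowSeq[i])))
})

#' Allele-class constructors for [PoolSpec()]
#'
#' Build single-row allele tables: the wild-type allele (reference window),
#' the precise HDR allele (donor edits applied via [hdrWindow()]), and
#' indel alleles (a deletion of \code{-delta} bases or an insertion of
#' \code{inserted} at a window position).
#'
#' @param spec the [AmpliconSpec-class] the pool refers to.
#' @param proportion mixture proportion of this allele.
#' @param label allele label (defaults shown per constructor).
#' @return one-row \code{data.frame(label, kind, windowSeq, proportion)}.
#' @name alleles
NULL

#' @rdname alleles
#' @export
alleleWT <- function(spec, proportion, label = "WT") {
  data.frame(label = label, kind = "WT",
             windowSeq = as.character(windowRef(spec)),
             proportion = proportion, stringsAsFactors = FALSE)
}

#' @rdname alleles
#' @export
alleleHDR <- function(spec, proportion, label = "HDR") {
  data.frame(label = label, kind = "HDR", windowSeq = hdrWindow(spec),
             proportion = proportion, stringsAsFactors = FALSE)
}

#' @rdname alleles
#' @param position 1-based window position at which the indel starts.
#' @param delta signed length change: negative deletes \code{-delta} bases
#'   starting at \code{position}; positive inserts \code{inserted} (of
#'   length \code{delta}) before \code{position}.
#' @param inserted inserted sequence (required when \code{delta > 0}).
#' @rdname alleles
#' @export
alleleIndel <- function(spec, proportion, position, delta, inserted = NULL,
                        label = sprintf("INDEL%+d", delta)) {
  wref <- as.character(windowRef(spec))
  L <- nchar(wref)
  if (delta == 0L) stop("'delta' must be nonzero", call. = FALSE)
  if (position < 1L || position > L)
    stop("'position' must lie within the window", call. = FALSE)
  if (delta < 0L) {
    if (position - delta - 1L > L)
      stop("deletion extends past the window end", call. = FALSE)
    w <- paste0(substr(wref, 1L, position - 1L),
                substr(wref, position - delta, L))
  } else {
    if (is.null(inserted) || nchar(inserted) != delta)
      stop("'inserted' must have length 'delta' for an insertion",
           call. = FALSE)
    w <- paste0(substr(wref, 1L, position - 1L), toupper(inserted),
                substr(wref, position, L))
  }
  data.frame(label = label, kind = "INDEL", windowSeq = w,
             proportion = proportion, stringsAsFactors = FALSE)
}

#' Apply i.i.d. substitution errors to sequences
#'
#' Each base is independently replaced, with probability \code{errorRate},
#' by one of the three other bases (uniformly). Length is preserved. Uses
#' the current RNG state; seed via \code{set.seed()} or let
#' [simulatePool()] manage seeding.
#'
#' @param seqs character vector of A/C/G/T sequences.
#' @param errorRate substitution probability per base, in [0, 1].
#' @return character vector of the same lengths.
#' @examples
#' set.seed(1); applyErrors("ACGTACGT", 0.5)
#' @export
applyErrors <- function(seqs, errorRate) {
  if (errorRate < 0 || errorRate > 1)
    stop("'errorRate' must be in [0, 1]", call. = FALSE)
  if (errorRate == 0 || !length(seqs)) return(seqs)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seqs, "")
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < errorRate)
  if (length(hit)) {
    ## uniform over the three alternatives: offset 1..3 from the original
    orig <- match(flat[hit], bases)
    off <- sample.int(3L, length(hit), replace = TRUE)
    flat[hit] <- bases[((orig - 1L + off) %% 4L) + 1L]
  }
  grp <- rep.int(seq_along(seqs), lens)
  unname(vapply(split(flat, grp), paste, "", collapse = ""))
}

## 1 bp sequencing indel errors (stress-test mode, off by default)
.applyIndelErrors <- function(seqs, rate) {
  if (rate == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1L]]
    hit <- which(stats::runif(length(chars)) < rate)
    if (!length(hit)) return(s)
    for (h in rev(hit)) {
      if (stats::runif(1) < 0.5)
        chars <- chars[-h]                       # deletion
      else
        chars <- append(chars, sample(bases, 1L), after = h)  # insertion
    }
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate an amplicon read pool with known composition
#'
#' Draws each read's allele from the mixture (multinomial), embeds the
#' allele window between the flanks in the full amplicon context, applies
#' substitution errors, and returns quality-scaled reads (constant Q30 —
#' qualities are not used by the default quantification) together with a
#' per-read truth table. Identical \code{PoolSpec} (including seed) gives
#' identical output. RNG state of the caller is left untouched.
#'
#' @param pool a [PoolSpec-class].
#' @return list with \code{reads}
#'   (\code{QualityScaledDNAStringSet}, named \code{read000001}, ...) and
#'   \code{truth} (\code{data.frame(readId, label, kind)}).
#' @examples
#' spec <- AmpliconSpec("toy",
#'   "GGGTTACCTGGAGTAACGTACGTACGTACGTGTCATGGAACCCC",
#'   "ACCTGGAGTA", "GTCATGGAAC", donorEdits = "3:G>T")
#' pool <- PoolSpec(spec, rbind(alleleHDR(spec, 0.9), alleleWT(spec, 0.1)),
#'                  nReads = 50, errorRate = 0, seed = 7)
#' sim <- simulatePool(pool)
#' table(sim$truth$label)
#' @export
simulatePool <- function(pool) {
  stopifnot(is(pool, "PoolSpec"))
  validObject(pool)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(pool@seed)

  spec <- pool@amplicon
  amp <- as.character(ampliconSeq(spec))
  lm <- matchPattern(leftFlank(spec), ampliconSeq(spec), fixed = TRUE)
  rm_ <- matchPattern(rightFlank(spec), ampliconSeq(spec), fixed = TRUE)
  pre <- substr(amp, 1L, end(lm)[1L])           # up to end of left flank
  post <- substr(amp, start(rm_)[1L], nchar(amp))  # right flank onwards

  al <- pool@alleles
  n <- pool@nReads
  alleleIdx <- sample.int(nrow(al), n, replace = TRUE, prob = al$proportion)
  fullSeqs <- paste0(pre, al$windowSeq, post)
  if (!is.na(pool@readLength)) {
    span <- nchar(pre) + nchar(al$windowSeq) + length(rightFlank(spec))
    if (any(pool@readLength < span))
      stop("readLength too short to span both flanks for every allele",
           call. = FALSE)
    fullSeqs <- substr(fullSeqs, 1L, pool@readLength)
  }
  seqs <- fullSeqs[alleleIdx]
  seqs <- applyErrors(seqs, pool@errorRate)
  if (pool@indelErrorRate > 0)
    seqs <- .applyIndelErrors(seqs, pool@indelErrorRate)

  ids <- sprintf("read%06d", seq_len(n))
  reads <- DNAStringSet(seqs)
  names(reads) <- ids
  qual <- PhredQuality(vapply(nchar(seqs), function(L)
    paste(rep("?", L), collapse = ""), ""))     # "?" = Phred 30
  list(reads = QualityScaledDNAStringSet(reads, qual),
       truth = data.frame(readId = ids, label = al$label[alleleIdx],
                          kind = al$kind[alleleIdx],
                          stringsAsFactors = FALSE))
}

#' Write a simulated pool to disk
#'
#' Writes the FASTQ (optionally gzipped), the truth table as TSV, and the
#' pool specification as JSON for provenance.
#'
#' @param sim result of [simulatePool()].
#' @param pool the [PoolSpec-class] that produced it.
#' @param dir output directory (created if needed).
#' @param gzip compress the FASTQ (default \code{TRUE}).
#' @return invisibly, named character vector of the paths written.
#' @export
writePool <- function(sim, pool, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, if (gzip) "reads.fastq.gz" else "reads.fastq")
  writeQualityScaledXStringSet(sim$reads, fq, compress = gzip)
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  specPath <- file.path(dir, "poolspec.json")
  de <- donorEdits(pool@amplicon)
  jsonlite::write_json(list(
    amplicon_id = ampliconId(pool@amplicon),
    amplicon_seq = as.character(ampliconSeq(pool@amplicon)),
    left_flank = as.character(leftFlank(pool@amplicon)),
    right_flank = as.character(rightFlank(pool@amplicon)),
    donor_edits = sprintf("%d:%s>%s", de$pos, de$ref, de$alt),
    alleles = pool@alleles,
    n_reads = pool@nReads, error_rate = pool@errorRate,
    indel_error_rate = pool@indelErrorRate,
    read_length = pool@readLength, seed = pool@seed
  ), specPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(fastq = fq, truth = truth, poolspec = specPath))
}
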