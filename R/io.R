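## File I/O: FASTQ/FASTA reading with structural validation, YAML
## configuration for amplicon and pool specs, and JSON/TSV summary output.

.openLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a FASTQ file into quality-scaled reads
#'
#' Reads plain or gzipped Sanger (Phred+33) FASTQ, validating the 4-line
#' record structure and the sequence/quality length agreement; parse
#' failures report the offending line number.
#'
#' @param path FASTQ file, \code{.gz} accepted.
#' @return \code{QualityScaledDNAStringSet} named by read id (text up to
#'   the first whitespace of the \code{@} line), in file order.
#' @export
readFastq <- function(path) {
  lines <- .openLines(path)
  if (!length(lines))
    return(QualityScaledDNAStringSet(DNAStringSet(), PhredQuality(character())))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("FASTQ parse error: %d lines is not a multiple of 4 (near line %d)",
                 length(lines), length(lines)), call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: record header must start with '@'",
                 idx[bad[1L]]), call. = FALSE)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: separator line must start with '+'",
                 idx[bad[1L]] + 2L), call. = FALSE)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: sequence and quality lengths differ (%d vs %d)",
                 idx[bad[1L]] + 3L, nchar(seqs[bad[1L]]),
                 nchar(quals[bad[1L]])), call. = FALSE)
  bad <- which(nchar(seqs) == 0L)
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: empty sequence",
                 idx[bad[1L]] + 1L), call. = FALSE)
  ids <- sub("^@", "", sub("\\s.*$", "", hdr))
  reads <- DNAStringSet(toupper(seqs))
  names(reads) <- ids
  QualityScaledDNAStringSet(reads, PhredQuality(quals))
}

#' Read a FASTA file
#'
#' @param path FASTA file, \code{.gz} accepted; multi-line records are
#'   joined and sequences uppercased.
#' @return named \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  lines <- .openLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("FASTA parse error: empty file", call. = FALSE)
  if (!startsWith(lines[1L], ">"))
    stop("FASTA parse error at line 1: missing '>' header", call. = FALSE)
  hdrIdx <- which(startsWith(lines, ">"))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdrIdx]))
  if (anyDuplicated(ids))
    stop("FASTA parse error: duplicate sequence id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  grp <- cumsum(startsWith(lines, ">"))
  seqs <- vapply(split(lines[-hdrIdx], grp[-hdrIdx]), paste, "",
                 collapse = "")
  out <- DNAStringSet(toupper(seqs))
  names(out) <- ids
  out
}

#' Read an amplicon specification from a YAML config
#'
#' Expected keys: \code{amplicon_id}, \code{left_flank},
#' \code{right_flank}, \code{donor_edits} (list of \code{"pos:REF>ALT"},
#' 1-based window positions; optional) and either \code{amplicon_seq}
#' (inline) or \code{amplicon_fasta} (path, resolved relative to the
#' config file; the FASTA must contain the id).
#'
#' @param path YAML config file.
#' @return An [AmpliconSpec-class].
#' @export
readAmpliconConfig <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (k in c("amplicon_id", "left_flank", "right_flank"))
    if (is.null(cfg[[k]]))
      stop("configuration error: missing key '", k, "' in ", path,
           call. = FALSE)
  if (!is.null(cfg$amplicon_seq)) {
    seq <- cfg$amplicon_seq
  } else if (!is.null(cfg$amplicon_fasta)) {
    fa <- cfg$amplicon_fasta
    if (!file.exists(fa))
      fa <- file.path(dirname(path), cfg$amplicon_fasta)
    set <- readFasta(fa)
    if (!cfg$amplicon_id %in% names(set))
      stop("configuration error: amplicon id '", cfg$amplicon_id,
           "' not found in ", fa, call. = FALSE)
    seq <- as.character(set[[cfg$amplicon_id]])
  } else {
    stop("configuration error: need 'amplicon_seq' or 'amplicon_fasta'",
         call. = FALSE)
  }
  edits <- if (is.null(cfg$donor_edits)) character() else
    unlist(cfg$donor_edits)
  AmpliconSpec(cfg$amplicon_id, seq, cfg$left_flank, cfg$right_flank,
               donorEdits = if (length(edits)) edits else
                 data.frame(pos = integer(), ref = character(),
                            alt = character()))
}

#' Read a pool-simulation specification from a YAML config
#'
#' Expected keys: an \code{amplicon} block (same keys as
#' [readAmpliconConfig()]) or \code{amplicon_config} (path to one);
#' \code{alleles}, a list of blocks with \code{kind} (WT/HDR/INDEL),
#' \code{proportion} and for indels \code{position}, \code{delta},
#' optional \code{inserted} and \code{label}; \code{n_reads};
#' \code{error_rate}; optional \code{indel_error_rate},
#' \code{read_length}, \code{seed}.
#'
#' @param path YAML config file.
#' @param seed overrides the config seed when not \code{NULL}.
#' @return A [PoolSpec-class].
#' @export
readPoolConfig <- function(path, seed = NULL) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  spec <- if (!is.null(cfg$amplicon_config)) {
    p <- cfg$amplicon_config
    if (!file.exists(p)) p <- file.path(dirname(path), cfg$amplicon_config)
    readAmpliconConfig(p)
  } else if (!is.null(cfg$amplicon)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(cfg$amplicon, tmp)
    readAmpliconConfig(tmp)
  } else stop("configuration error: need 'amplicon' or 'amplicon_config'",
              call. = FALSE)
  if (is.null(cfg$alleles) || !length(cfg$alleles))
    stop("configuration error: no alleles defined", call. = FALSE)
  rows <- lapply(cfg$alleles, function(a) {
    kind <- toupper(a$kind)
    if (is.null(a$proportion))
      stop("configuration error: allele without proportion", call. = FALSE)
    switch(kind,
      WT = alleleWT(spec, a$proportion,
                    label = if (is.null(a$label)) "WT" else a$label),
      HDR = alleleHDR(spec, a$proportion,
                      label = if (is.null(a$label)) "HDR" else a$label),
      INDEL = {
        args <- list(spec, a$proportion, position = a$position,
                     delta = a$delta, inserted = a$inserted)
        if (!is.null(a$label)) args$label <- a$label
        do.call(alleleIndel, args)
      },
      stop("configuration error: unknown allele kind '", a$kind, "'",
           call. = FALSE))
  })
  PoolSpec(spec, do.call(rbind, rows),
           nReads = cfg$n_reads,
           errorRate = if (is.null(cfg$error_rate)) 0 else cfg$error_rate,
           indelErrorRate = if (is.null(cfg$indel_error_rate)) 0 else
             cfg$indel_error_rate,
           readLength = if (is.null(cfg$read_length)) NA_integer_ else
             cfg$read_length,
           seed = if (!is.null(seed)) seed else
             if (is.null(cfg$seed)) 1L else cfg$seed)
}

#' Write an editing summary to disk
#'
#' Writes \code{summary.json} (all counts and frequencies; \code{NaN}
#' serialized as \code{null} together with an \code{undefined_frequencies}
#' flag), \code{base_freq.tsv} (one row per window position, columns
#' \code{pos, A, C, G, T, N}) and \code{run_info.json} (package version
#' and parameter echo).
#'
#' @param summary an [EditingSummary-class].
#' @param outdir output directory (created if needed).
#' @return invisibly, named character vector of paths written.
#' @seealso [readSummary()] for the round trip.
#' @export
writeSummary <- function(summary, outdir) {
  stopifnot(is(summary, "EditingSummary"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  undef <- summary@nAnalyzed == 0L
  if (undef)
    warning("frequencies are undefined (no analyzed reads); writing null",
            call. = FALSE)
  js <- list(
    amplicon_id = summary@ampliconId,
    n_total = summary@nTotal, n_excluded = summary@nExcluded,
    n_analyzed = summary@nAnalyzed, n_indel = summary@nIndel,
    n_intact = summary@nIntact, n_insertion = summary@nInsertion,
    n_deletion = summary@nDeletion,
    indel_freq = summary@indelFreq,
    insertion_freq = summary@insertionFreq,
    deletion_freq = summary@deletionFreq,
    programmed_edit_freq = summary@programmedEditFreq,
    programmed_edit_freq_intact = summary@programmedEditFreqIntact,
    donor_edit_freq = as.list(summary@donorEditFreq),
    indel_sizes = as.list(summary@indelSizes),
    undefined_frequencies = undef
  )
  sumPath <- file.path(outdir, "summary.json")
  jsonlite::write_json(js, sumPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  bf <- as.data.frame(summary@baseFreq)
  bf <- cbind(pos = seq_len(nrow(bf)), bf)
  bfPath <- file.path(outdir, "base_freq.tsv")
  utils::write.table(bf, bfPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  infoPath <- file.path(outdir, "run_info.json")
  jsonlite::write_json(list(
    tool = "flankQuant",
    version = as.character(utils::packageVersion("flankQuant")),
    params = summary@params
  ), infoPath, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(summary = sumPath, base_freq = bfPath, run_info = infoPath))
}

#' Read back a written editing summary
#'
#' Reconstructs an [EditingSummary-class] from a [writeSummary()] output
#' directory; counts round-trip exactly.
#'
#' @param outdir directory previously written by [writeSummary()].
#' @return An [EditingSummary-class].
#' @export
readSummary <- function(outdir) {
  js <- jsonlite::read_json(file.path(outdir, "summary.json"),
                            simplifyVector = TRUE)
  bf <- utils::read.table(file.path(outdir, "base_freq.tsv"),
                          header = TRUE, sep = "\t",
                          check.names = FALSE)
  mat <- as.matrix(bf[, c("A", "C", "G", "T", "N"), drop = FALSE])
  dimnames(mat) <- list(NULL, c("A", "C", "G", "T", "N"))
  info <- jsonlite::read_json(file.path(outdir, "run_info.json"),
                              simplifyVector = TRUE)
  asNum <- function(x) if (is.null(x)) NaN else as.numeric(x)
  donor <- unlist(js$donor_edit_freq)
  donor <- if (is.null(donor)) numeric() else
    vapply(donor, asNum, 1)
  sizes <- unlist(js$indel_sizes)
  sizes <- if (is.null(sizes)) integer() else {
    s <- as.integer(sizes); names(s) <- names(sizes); s
  }
  params <- as.list(info$params)
  if (is.null(params$minMeanQ)) params["minMeanQ"] <- list(NULL)
  new("EditingSummary", ampliconId = js$amplicon_id,
      nTotal = as.integer(js$n_total), nExcluded = as.integer(js$n_excluded),
      nAnalyzed = as.integer(js$n_analyzed), nIndel = as.integer(js$n_indel),
      nIntact = as.integer(js$n_intact),
      nInsertion = as.integer(js$n_insertion),
      nDeletion = as.integer(js$n_deletion),
      indelFreq = asNum(js$indel_freq),
      insertionFreq = asNum(js$insertion_freq),
      deletionFreq = asNum(js$deletion_freq),
      baseFreq = mat,
      programmedEditFreq = asNum(js$programmed_edit_freq),
      programmedEditFreqIntact = asNum(js$programmed_edit_freq_intact),
      donorEditFreq = donor, indelSizes = sizes,
      params = params)
}

#' Bundled synthetic TIE2 L914F amplicon fixture
#'
#' Loads the amplicon specification shipped with the package: a synthetic
#' stand-in for the TIE2 exon-17 amplicon, delimited by the published PCR
#' primers (F: CAGGGCCACTGATGAGTCGAT, R: TCGGCAGCGAAGTGAAGGAG) with a
#' 20 bp editing window whose donor edit is a C>T substitution turning a
#' CTC leucine codon into TTC phenylalanine — the L914F-style change. The
#' internal sequence between the primers is invented (the true genomic
#' context is not bundled); it exists so the pipeline has a realistic,
#' self-contained configuration to run and simulate against.
#'
#' @return An [AmpliconSpec-class].
#' @examples
#' tie2Example()
#' @export
tie2Example <- function() {
  readAmpliconConfig(system.file("extdata", "tie2_l914f_synthetic.yaml",
                                 package = "flankQuant", mustWork = TRUE))
}
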