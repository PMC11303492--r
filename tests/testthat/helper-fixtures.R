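# Shared fixtures and the independent brute-force flank-search oracle.
# The oracle deliberately avoids Biostrings matching: it enumerates every
# placement with plain character comparisons and applies the selection rule
# (min total mismatches; ties -> leftmost left start, then leftmost right
# start; forward orientation unless reverse complement is strictly better).

BASES <- c("A", "C", "G", "T")

randDNA <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcompChr <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

mutateAt <- function(s, pos) {
  ch <- strsplit(s, "")[[1L]]
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# toy amplicon: 10 bp flanks around a 6 bp window with one donor edit
toySpec <- function() {
  AmpliconSpec("toy",
    ampliconSeq = paste0("GGATC", "ACCTGGAGTA", "ACGTGA", "GTCATGGAAC",
                         "TTGCA"),
    leftFlank = "ACCTGGAGTA", rightFlank = "GTCATGGAAC",
    donorEdits = "3:G>T")
}

# toy amplicon with a two-position donor edit
toySpec2 <- function() {
  AmpliconSpec("toy2",
    ampliconSeq = paste0("GGATC", "ACCTGGAGTA", "ACGTGA", "GTCATGGAAC",
                         "TTGCA"),
    leftFlank = "ACCTGGAGTA", rightFlank = "GTCATGGAAC",
    donorEdits = c("3:G>T", "5:G>C"))
}

toyRead <- function(spec, window = as.character(windowRef(spec))) {
  paste0(as.character(leftFlank(spec)), window,
         as.character(rightFlank(spec)))
}

## ---- brute-force oracle --------------------------------------------------

.bruteMM <- function(readChars, flankChars) {
  n <- length(readChars); w <- length(flankChars)
  if (n < w) return(integer(0))
  starts <- seq_len(n - w + 1L)
  mm <- integer(length(starts))
  for (j in seq_len(w))
    mm <- mm + (readChars[starts + j - 1L] != flankChars[j])
  mm
}

.bruteBestOne <- function(read, lf, rf, maxMM) {
  rc <- strsplit(read, "")[[1L]]
  mmL <- .bruteMM(rc, strsplit(lf, "")[[1L]])
  mmR <- .bruteMM(rc, strsplit(rf, "")[[1L]])
  wL <- nchar(lf)
  best <- NULL
  for (l in which(mmL <= maxMM)) {
    for (r in which(mmR <= maxMM)) {
      if (l + wL > r) next
      tot <- mmL[l] + mmR[r]
      if (is.null(best) || tot < best$total ||
          (tot == best$total && (l < best$leftStart ||
            (l == best$leftStart && r < best$rightStart))))
        best <- list(leftStart = l, rightStart = r,
                     leftMismatches = mmL[l], rightMismatches = mmR[r],
                     total = tot)
    }
  }
  best
}

bruteFindFlanks <- function(read, spec, maxMismatch = 1L, noRC = FALSE) {
  lf <- as.character(leftFlank(spec))
  rf <- as.character(rightFlank(spec))
  fwd <- .bruteBestOne(read, lf, rf, maxMismatch)
  rev <- if (noRC) NULL else
    .bruteBestOne(revcompChr(read), lf, rf, maxMismatch)
  pick <- NULL; orientation <- NA_character_
  if (!is.null(fwd) && (is.null(rev) || rev$total >= fwd$total)) {
    pick <- fwd; orientation <- "forward"
  } else if (!is.null(rev)) {
    pick <- rev; orientation <- "reverse_complement"
  }
  if (is.null(pick)) return(NULL)
  list(leftStart = pick$leftStart, rightStart = pick$rightStart,
       leftMismatches = pick$leftMismatches,
       rightMismatches = pick$rightMismatches, orientation = orientation)
}

# random read generator for oracle-equivalence checks: a planted
# flank/window/flank cassette (with 0-2 mismatches per flank) inside
# random context, in either orientation, plus occasional pure-noise reads
randomOracleRead <- function(spec, maxLen = 60L) {
  lf <- as.character(leftFlank(spec))
  rf <- as.character(rightFlank(spec))
  if (runif(1) < 0.15) return(randDNA(sample(20:maxLen, 1L)))
  winLen <- sample(0:8, 1L)
  lfm <- mutateAt(lf, sample(seq_len(nchar(lf)), sample(0:2, 1L)))
  rfm <- mutateAt(rf, sample(seq_len(nchar(rf)), sample(0:2, 1L)))
  core <- paste0(lfm, randDNA(winLen), rfm)
  padTot <- max(0L, min(maxLen - nchar(core), sample(0:12, 1L)))
  padL <- sample(0:padTot, 1L)
  read <- paste0(randDNA(padL), core, randDNA(padTot - padL))
  if (runif(1) < 0.5) read <- revcompChr(read)
  read
}

# deterministic enriched-pool spec mirroring the bundled simulation profile
enrichedPool <- function(spec, nReads, seed, errorRate = 0.001) {
  PoolSpec(spec,
           rbind(alleleHDR(spec, 0.985),
                 alleleIndel(spec, 0.010, position = 2, delta = -4),
                 alleleWT(spec, 0.005)),
           nReads = nReads, errorRate = errorRate, seed = seed)
}

# random four-class mixture over the toy amplicon with a random error rate
randomPool <- function(spec, nReads, seed, errorRate = NULL) {
  set.seed(seed)
  if (is.null(errorRate)) errorRate <- runif(1, 0, 0.05)
  p <- as.vector(stats::rmultinom(1, 100, rep(1, 4))) / 100
  p <- (p + 0.05) / sum(p + 0.05)   # keep all four classes present
  al <- rbind(alleleHDR(spec, p[1]), alleleWT(spec, p[2]),
              alleleIndel(spec, p[3], position = 2, delta = -3),
              alleleIndel(spec, p[4], position = 3, delta = 1,
                          inserted = "T", label = "ins1"))
  PoolSpec(spec, al, nReads = nReads, errorRate = errorRate, seed = seed)
}

tie2Spec <- function() tie2Example()

# run a simulated pool through the full FASTQ write/read round trip
readFastqFromSim <- function(sim, pool) {
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  writePool(sim, pool, d, gzip = TRUE)
  readFastq(file.path(d, "reads.fastq.gz"))
}
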