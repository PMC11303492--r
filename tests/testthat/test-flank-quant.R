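test_that("exact reads give the identity flank match", {
  spec <- toySpec()
  fm <- findFlanks(toyRead(spec), spec)
  expect_identical(fm$leftStart, 1L)
  expect_identical(fm$rightStart, 1L + 10L + 6L)
  expect_identical(fm$leftMismatches, 0L)
  expect_identical(fm$rightMismatches, 0L)
  expect_identical(fm$orientation, "forward")
})

test_that("per-flank mismatch allowance is enforced", {
  spec <- toySpec()
  read <- toyRead(spec)
  # one mismatch in each flank is tolerated at maxMismatch = 1
  set.seed(11)
  r1 <- mutateAt(read, c(4L, nchar(read) - 3L))
  fm <- findFlanks(r1, spec, maxMismatch = 1)
  expect_identical(fm$leftMismatches, 1L)
  expect_identical(fm$rightMismatches, 1L)
  # two mismatches inside the left flank exclude the read
  r2 <- mutateAt(read, c(2L, 5L))
  expect_null(findFlanks(r2, spec, maxMismatch = 1))
  expect_identical(classifyRead(r2, spec)$category, "excluded")
  # ...but maxMismatch = 2 recovers it
  expect_false(is.null(findFlanks(r2, spec, maxMismatch = 2)))
  # an N in a flank counts as a mismatch
  rN <- paste0("ACCTGGAGTN", "ACGTGA", "GTCATGGAAC")
  fmN <- findFlanks(rN, spec)
  expect_identical(fmN$leftMismatches, 1L)
  expect_null(findFlanks(sub("GGAGTN", "GGNGTN", rN), spec))
})

test_that("reverse-complement reads recover the identical window", {
  spec <- toySpec()
  read <- toyRead(spec)
  rcRead <- revcompChr(read)
  fm <- findFlanks(rcRead, spec)
  expect_identical(fm$orientation, "reverse_complement")
  expect_identical(fm$leftMismatches + fm$rightMismatches, 0L)
  cls <- classifyRead(rcRead, spec)
  expect_identical(cls$observedWindow, as.character(windowRef(spec)))
  expect_identical(cls$category, "intact")
  # disabling reverse-complement search excludes the read
  expect_null(findFlanks(rcRead, spec, noRC = TRUE))
})

test_that("window length deviations are called as signed indels", {
  spec <- toySpec()  # 6 bp window
  del3 <- classifyRead(toyRead(spec, "ACG"), spec)
  expect_identical(del3$category, "indel")
  expect_identical(del3$lengthDelta, -3L)
  ins2 <- classifyRead(toyRead(spec, "ACGTGATC"), spec)
  expect_identical(ins2$category, "indel")
  expect_identical(ins2$lengthDelta, 2L)
  # full window deletion: flanks abut
  del6 <- classifyRead(toyRead(spec, ""), spec)
  expect_identical(del6$lengthDelta, -6L)
  expect_identical(del6$observedWindow, "")
  # a substitution at the donor position is intact, not an indel
  sub1 <- classifyRead(toyRead(spec, "ACTTGA"), spec)
  expect_identical(sub1$category, "intact")
  expect_identical(sub1$observedWindow, "ACTTGA")
})

test_that("empty or invalid reads signal invalid input", {
  spec <- toySpec()
  expect_error(findFlanks("", spec), "empty read")
  expect_error(classifyReads(c("ACGT", ""), spec), "empty read")
  expect_error(classifyReads(1:3, spec), "character")
  expect_error(classifyReads("ACGT", spec, maxMismatch = -1), ">= 0")
})

test_that("quantifyPool reproduces a hand-counted toy pool", {
  spec <- toySpec()
  hdr <- toyRead(spec, hdrWindow(spec))
  reads <- c(rep(hdr, 8),
             toyRead(spec, "ACGT"),                       # 2 bp deletion
             paste0("TTTTTTTTTT", "ACGTGA", "GTCATGGAAC")) # dead left flank
  summ <- quantifyPool(reads, spec)
  expect_identical(nTotal(summ), 10L)
  expect_identical(nExcluded(summ), 1L)
  expect_identical(nAnalyzed(summ), 9L)
  expect_identical(nIndel(summ), 1L)
  expect_identical(nIntact(summ), 8L)
  expect_equal(indelFreq(summ), 1 / 9)
  expect_equal(deletionFreq(summ), 1 / 9)
  expect_equal(insertionFreq(summ), 0)
  expect_equal(programmedEditFreq(summ), 8 / 9)
  expect_identical(indelSizes(summ), c(`-2` = 1L))
})

test_that("empty pools yield zero counts and NaN frequencies", {
  spec <- toySpec()
  summ <- quantifyPool(character(), spec)
  expect_identical(nTotal(summ), 0L)
  expect_identical(nAnalyzed(summ), 0L)
  expect_true(is.nan(indelFreq(summ)))
  expect_true(is.nan(programmedEditFreq(summ)))
  expect_true(all(baseFreq(summ) == 0))
  # non-empty pool with nothing analyzable warns rather than errors
  expect_warning(quantifyPool("TTTTTTTTTTTTTTTTTTTTTTTTTT", spec),
                 "undefined")
})

test_that("an all-wild-type pool is one-hot on the reference window", {
  spec <- toySpec()
  summ <- quantifyPool(rep(toyRead(spec), 5), spec)
  expect_equal(programmedEditFreq(summ), 0)
  expect_equal(indelFreq(summ), 0)
  bf <- baseFreq(summ)
  wref <- strsplit(as.character(windowRef(spec)), "")[[1L]]
  for (i in seq_along(wref)) {
    expect_equal(unname(bf[i, wref[i]]), 1)
    expect_equal(sum(bf[i, ]), 1)
  }
})

test_that("base frequency matrix matches hand counts", {
  m <- baseFrequencyMatrix(c("ACG", "ACG", "ACT"), "ACG")
  expect_equal(dim(m), c(3L, 5L))
  expect_equal(unname(m[3, "G"]), 2 / 3)
  expect_equal(unname(m[3, "T"]), 1 / 3)
  expect_equal(rowSums(m), rep(1, 3), ignore_attr = TRUE)
  # N occupies its own column and rows still sum to 1
  mN <- baseFrequencyMatrix(c("ANG", "ACG"), "ACG")
  expect_equal(unname(mN[2, "N"]), 0.5)
  expect_equal(rowSums(mN), rep(1, 3), ignore_attr = TRUE)
  # reference-only input is one-hot
  m1 <- baseFrequencyMatrix("ACG", "ACG")
  expect_equal(unname(m1[cbind(1:3, match(c("A","C","G"), colnames(m1)))]),
               rep(1, 3))
  expect_error(baseFrequencyMatrix(c("AC", "ACG"), "ACG"), "length")
})

test_that("programmed-edit frequency requires all donor positions", {
  spec2 <- toySpec2()  # edits 3:G>T and 5:G>C; window ACGTGA
  # windows: both edits, only first, only second, none
  wins <- c("ACTTCA", "ACTTGA", "ACGTCA", "ACGTGA")
  p <- programmedEditFrequency(wins, spec2, nAnalyzed = 5)
  expect_equal(p$freq, 1 / 5)
  expect_equal(unname(p$perPosition["3:G>T"]), 2 / 5)
  expect_equal(unname(p$perPosition["5:G>C"]), 2 / 5)
  expect_equal(p$freqIntact, 1 / 4)
  # a spec without donor edits is a configuration error
  noEdit <- AmpliconSpec("x", ampliconSeq(toySpec()), "ACCTGGAGTA",
                         "GTCATGGAAC")
  expect_error(programmedEditFrequency(wins, noEdit, 5), "configuration")
  expect_true(is.na(programmedEditFreq(quantifyPool(toyRead(spec2), noEdit))))
})
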