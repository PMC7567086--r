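test_that("readBed parses BED3/BED6/narrowPeak and converts coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo", "# a comment",
               "chr1\t100\t200",
               "chr2\t0\t50"), f)
  gr <- readBed(f)
  expect_length(gr, 2)
  expect_equal(GenomicRanges::start(gr), c(101, 1))
  expect_equal(GenomicRanges::end(gr), c(200, 50))
  expect_equal(GenomicRanges::width(gr)[1], 100)
  expect_equal(as.character(GenomicRanges::strand(gr)), c("*", "*"))

  # the PER-cluster browser span as a BED6 line: width 645, plus strand
  writeLines("chr17\t8138880\t8139525\tPER\t0\t+", f)
  gr <- readBed(f)
  expect_equal(GenomicRanges::width(gr), 645)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")
  expect_equal(gr$name, "PER")

  writeLines("chr1\t10\t60\tp1\t900\t-\t5.5\t3.2\t1.1\t25", f)
  np <- readBed(f, dialect = "narrowPeak")
  expect_equal(np$signalValue, 5.5)
  expect_equal(np$peak, 25L)

  writeLines(character(0), f)
  expect_length(readBed(f), 0)
})

test_that("readBed rejects malformed lines, naming the line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t10", "chr1\tx\t20"), f)
  expect_error(readBed(f), "line 2")
  writeLines(c("chr1\t100\t100"), f)
  expect_error(readBed(f), "line 1.*end.*start")
  writeLines(c("chr1\t100"), f)
  expect_error(readBed(f), "line 1")
  expect_error(readBed(tempfile()), "not found")
})

test_that("BED write/read round-trips are bit-exact", {
  set.seed(1)
  s <- sort(sample.int(1e6, 20))
  gr <- gri("chr3", s, s + sample.int(500, 20),
            strand = sample(c("+", "-", "*"), 20, TRUE))
  gr$name <- sprintf("iv%02d", 1:20)
  gr$score <- sample.int(1000, 20)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeBed(gr, f1)
  back <- readBed(f1)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gr)))
  expect_equal(back$name, gr$name)
  writeBed(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("GFF keeps 1-based inclusive coordinates and round-trips", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrL\tsrc\tLAD\t101\t200\t.\t+\t.\tID=lad1"), f)
  gr <- readGff(f)
  expect_equal(GenomicRanges::start(gr), 101)
  expect_equal(GenomicRanges::end(gr), 200)
  expect_equal(GenomicRanges::width(gr), 100)
  expect_equal(gr$type, "LAD")

  f2 <- withr::local_tempfile()
  writeGff(gr, f2)
  expect_identical(readLines(f2)[-1], readLines(f)[-1])

  writeLines("##gff-version 3", f)
  expect_length(readGff(f), 0)
  writeLines("chrL\tsrc\tLAD\t101", f)
  expect_error(readGff(f), "line 1")
  writeLines("chrL\tsrc\tLAD\t201\t200\t.\t+\t.\t.", f)
  expect_error(readGff(f), "end < start")
})

test_that("FASTA write-then-read is the identity", {
  set.seed(2)
  seqs <- Biostrings::DNAStringSet(vapply(1:5, function(i) randomDna(80),
                                          character(1)))
  names(seqs) <- paste0("s", 1:5)
  f <- withr::local_tempfile(fileext = ".fa")
  writeFasta(seqs, f)
  back <- readFasta(f)
  expect_identical(names(back), names(seqs))
  expect_identical(as.character(back), as.character(seqs))
})

test_that("filterPeaksByLength is strict at the threshold and idempotent", {
  gr <- gri("chr1", c(1, 1, 1), c(500, 1000, 1001))
  out <- filterPeaksByLength(gr)
  expect_equal(GenomicRanges::width(out), c(500, 1000))
  expect_equal(attr(out, "removed"), 1L)

  again <- filterPeaksByLength(out)
  expect_equal(GenomicRanges::width(again), GenomicRanges::width(out))
  expect_equal(attr(again, "removed"), 0L)

  short <- gri("chr1", 1:10, (1:10) + 99)
  expect_equal(GenomicRanges::width(filterPeaksByLength(short)),
               GenomicRanges::width(short))

  # a set built with exactly 2% of peaks drawn longer than 1 kb
  set.seed(3)
  lens <- c(sample(100:1000, 4900, TRUE), sample(1001:5000, 100, TRUE))
  lens <- sample(lens)
  mix <- gri("chr1", seq_along(lens) * 6000, seq_along(lens) * 6000 + lens - 1)
  kept <- filterPeaksByLength(mix)
  expect_equal(attr(kept, "removed") / length(mix), 0.02)
})

test_that("overlapBp matches the spec examples and is symmetric", {
  a <- gri("chr1", 101, 200)  # BED [100,200)
  b <- gri("chr1", 151, 250)  # BED [150,250)
  expect_equal(overlapBp(a, b), 50L)
  expect_equal(overlapBp(b, a), 50L)
  expect_equal(overlapBp(gri("chr1", 101, 200), gri("chr1", 201, 300)), 0L)
  expect_equal(overlapBp(gri("chr1", 101, 200), gri("chr2", 101, 200)), 0L)
})

test_that("overlapBp agrees with a per-base set-intersection oracle", {
  set.seed(4)
  for (k in 1:1000) {
    sq <- sample(c("chr1", "chr1", "chr2"), 2, TRUE)
    s <- sample.int(500, 2); w <- sample.int(80, 2)
    a <- gri(sq[1], s[1], s[1] + w[1])
    b <- gri(sq[2], s[2], s[2] + w[2])
    expect_identical(overlapBp(a, b), as.integer(bruteOverlapBp(a, b)))
  }
})

test_that("signedDistance follows gap arithmetic and the anchor strand", {
  # anchor BED [1000,1100) +, other [900,950): 50-bp gap upstream
  anchor <- gri("chr1", 1001, 1100, "+")
  other <- gri("chr1", 901, 950)
  expect_equal(signedDistance(anchor, other), -50L)
  # minus-strand anchor: the same interval is downstream
  expect_equal(signedDistance(gri("chr1", 1001, 1100, "-"), other), 50L)
  # overlap collapses to zero
  expect_equal(signedDistance(anchor, gri("chr1", 1051, 1060)), 0L)
  expect_error(signedDistance(anchor, gri("chr2", 901, 950)), "different")
  # orientation can be disabled
  expect_equal(signedDistance(gri("chr1", 1001, 1100, "-"), other,
                              orientByStrand = FALSE), -50L)
})

test_that("signedDistance is zero exactly for overlap or abutment", {
  set.seed(5)
  for (k in 1:500) {
    s <- sample.int(400, 2); w <- sample.int(60, 2)
    a <- gri("chr1", s[1], s[1] + w[1], sample(c("+", "-"), 1))
    b <- gri("chr1", s[2], s[2] + w[2])
    d <- signedDistance(a, b)
    ov <- overlapBp(a, b)
    abut <- GenomicRanges::start(b) == GenomicRanges::end(a) + 1L ||
      GenomicRanges::start(a) == GenomicRanges::end(b) + 1L
    expect_identical(d == 0L, ov >= 1L || abut)
  }
})
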