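test_that("scoreWindow sums per-position weights and skips ambiguity", {
  p <- toyPwm()
  expect_equal(scoreWindow(p, consensusSequence(p)), maxScore(p))
  expect_equal(scoreWindow(p, "AAAAAA"), 2.5 - 5 * 4)  # one consensus A at pos 3
  u <- PWMotif(matrix(0.5, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL)),
               "uniform")
  expect_equal(scoreWindow(u, "ACGTA"), 5 * 0.5)
  expect_true(is.na(scoreWindow(p, "GCANGC")))
  expect_error(scoreWindow(p, "GCAT"), "length")
})

test_that("scanPwm equals exhaustive brute-force enumeration on both strands", {
  set.seed(31)
  p <- toyPwm(threshold = -2)   # permissive threshold exercises many windows
  for (rep_ in 1:25) {
    s <- randomDna(sample(40:120, 1))
    got <- scanPwm(p, stats::setNames(Biostrings::DNAStringSet(s), "x"))
    want <- bruteScan(p, s, -2)
    got <- got[order(got$start, got$strand), ]
    want <- want[order(want$start, want$strand), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("forward window scores agree with Biostrings as an external oracle", {
  set.seed(32)
  p <- toyPwm()
  s <- randomDna(200)
  subj <- Biostrings::DNAString(s)
  for (st in seq_len(200 - pwmWidth(p) + 1)) {
    expect_equal(scoreWindow(p, substr(s, st, st + pwmWidth(p) - 1)),
                 unname(Biostrings::PWMscoreStartingAt(p@weights, subj, st)),
                 tolerance = 1e-9)
  }
})

test_that("thresholds are strict and hit sets are nested as they rise", {
  set.seed(33)
  p <- toyPwm()
  seqs <- stats::setNames(Biostrings::DNAStringSet(
    vapply(1:10, function(i) {
      s <- randomDna(80)
      substr(s, 20, 25) <- consensusSequence(p)
      s
    }, character(1))), paste0("s", 1:10))
  expect_equal(nrow(scanPwm(p, seqs, threshold = maxScore(p))), 0)
  prev <- NULL
  for (th in c(-5, 0, 5, 10)) {
    h <- scanPwm(p, seqs, threshold = th)
    expect_true(all(h$score > th))
    if (!is.null(prev)) {
      expect_true(all(paste(h$tdna_id, h$start, h$strand) %in% prev))
    }
    prev <- paste(h$tdna_id, h$start, h$strand)
  }
})

test_that("palindromic PWMs yield mirrored equal-scoring hits on both strands", {
  set.seed(34)
  p <- palindromicPwm(threshold = -10)   # report everything
  s <- randomDna(60)
  h <- scanPwm(p, stats::setNames(Biostrings::DNAStringSet(s), "x"))
  ph <- h[h$strand == "p", ]
  nh <- h[h$strand == "n", ]
  expect_equal(nrow(ph), nrow(nh))
  m <- merge(ph, nh, by = "start")
  expect_equal(nrow(m), nrow(ph))   # same windows
  expect_equal(m$score.x, m$score.y, tolerance = 1e-12)
})

test_that("n-strand hits score the reverse complement of the forward window", {
  set.seed(35)
  p <- toyPwm(threshold = -6)
  s <- randomDna(90)
  h <- scanPwm(p, stats::setNames(Biostrings::DNAStringSet(s), "x"))
  nh <- h[h$strand == "n", ]
  for (k in seq_len(nrow(nh))) {
    fwd <- substr(s, nh$start[k], nh$end[k])
    expect_equal(nh$matched[k], revcompChar(fwd))
    expect_equal(nh$score[k], scoreWindow(p, revcompChar(fwd)))
  }
})

test_that("genomic hit coordinates respect the locus strand", {
  p <- toyPwm()
  sq <- paste0(strrep("A", 10), consensusSequence(p), strrep("A", 20))
  for (std in c("+", "-")) {
    gr <- gri("chr5", 2001, 2001 + nchar(sq) - 1, std, tdna_id = "t1")
    td <- TDNASet(gr, sequences = stats::setNames(
      Biostrings::DNAStringSet(sq), "t1"))
    h <- scanPwm(p, td)
    h <- h[h$strand == "p" & h$start == 11, ]
    expect_equal(nrow(h), 1)
    if (std == "+") {
      expect_equal(h$g_start, 2001 + 10)
    } else {
      expect_equal(h$g_end, GenomicRanges::end(gr) - 10)
    }
    expect_equal(h$g_end - h$g_start + 1L, pwmWidth(p))
  }
})

test_that("short sequences are skipped with a warning, not scored", {
  p <- toyPwm()
  seqs <- stats::setNames(Biostrings::DNAStringSet(c("ACG", "ACGTACGTAC")), c("a", "b"))
  expect_warning(h <- scanPwm(p, seqs, threshold = -100), "shorter")
  expect_true(all(h$tdna_id == "b"))
})

test_that("confirmHits flags overlaps with CTCF peaks and summarizes", {
  p <- toyPwm()
  sq <- paste0(strrep("T", 8), consensusSequence(p), strrep("T", 8))
  gr <- gri("chr5", c(1001, 3001), c(1001, 3001) + nchar(sq) - 1, "+",
            tdna_id = c("t1", "t2"))
  td <- TDNASet(gr, sequences = stats::setNames(
    Biostrings::DNAStringSet(c(sq, sq)), c("t1", "t2")))
  hits <- scanPwm(p, td)
  expect_equal(sort(unique(hits$tdna_id)), c("t1", "t2"))

  # peak exactly covering the t1 hit confirms it; t2 stays unconfirmed
  res <- confirmHits(hits, gri("chr5", 1009, 1014), tdnas = td)
  h1 <- res$hits
  expect_true(all(h1$chip_confirmed[h1$tdna_id == "t1" & h1$strand == "p"]))
  expect_false(any(h1$chip_confirmed[h1$tdna_id == "t2"]))
  expect_true(all(h1$in_tdna))
  expect_equal(unname(res$summary["n_loci_with_hits"]), 2L)

  # no peaks supplied: zero confirmed, every hit retained
  res0 <- confirmHits(hits, GenomicRanges::GRanges())
  expect_equal(nrow(res0$hits), nrow(hits))
  expect_equal(unname(res0$summary["n_confirmed"]), 0L)
})

test_that("structural regions partition hits and respect the tie-break", {
  seg <- canonicalSegmentation(72)
  td <- TDNASet(gri("chr5", 5001, 5072, "+", tdna_id = "t1"),
                sequences = stats::setNames(
                  Biostrings::DNAStringSet(strrep("A", 72)), "t1"),
                structures = list(t1 = seg))
  mids <- floor((IRanges::start(seg) + IRanges::end(seg)) / 2)
  names(mids) <- names(seg)
  mkhit <- function(st) data.frame(tdna_id = "t1", start = st, end = st,
                                   strand = "p", matched = "A", score = 9)
  lab <- function(st) assignStructuralRegion(mkhit(st), td)$structural_region
  expect_equal(lab(1), "5prime-D")                       # 5' terminal
  expect_equal(lab(mids[["dloop"]] - 1), "5prime-D")
  expect_equal(lab(mids[["dloop"]]), "D-anticodon")      # tie -> downstream
  expect_equal(lab(mids[["anticodon"]] - 1), "D-anticodon")
  expect_equal(lab(mids[["anticodon"]]), "anticodon-T")
  expect_equal(lab(mids[["tloop"]] - 1), "anticodon-T")  # variable loop folded in
  expect_equal(lab(mids[["tloop"]]), "T-3prime")
  expect_equal(lab(72), "T-3prime")

  # missing structure -> unassigned
  td0 <- TDNASet(gri("chr5", 5001, 5072, "+", tdna_id = "t1"))
  expect_equal(assignStructuralRegion(mkhit(10), td0)$structural_region,
               "unassigned")

  # all assigned hits get exactly one of the four labels
  set.seed(36)
  hits <- do.call(rbind, lapply(sample(1:72, 30, TRUE), mkhit))
  got <- assignStructuralRegion(hits, td)$structural_region
  expect_true(all(got %in% c("5prime-D", "D-anticodon", "anticodon-T",
                             "T-3prime")))
  expect_equal(sum(table(got)), nrow(hits))
})

test_that("cohesin colocalization requires every factor in the same cell", {
  td <- mk <- TDNASet(gri("chr1", c(1000, 5000, 9000), c(1071, 5071, 9071), "+",
                          tdna_id = c("t1", "t2", "t3")))
  cover <- function(s) gri("chr1", s, s + 71)
  pc <- PeakCollection(list(
    cA = list(CTCF = c(cover(1000), cover(5000)),
              RAD21 = c(cover(1000), cover(5000)),
              SMC3 = cover(1000)),
    cB = list(CTCF = cover(1000), RAD21 = cover(1000), SMC3 = cover(1000))))
  res <- cohesinColocalization(td, pc)
  # t2 has CTCF+RAD21 but never SMC3 -> excluded
  expect_false("t2" %in% res$anyCell)
  # t1 colocalized in both cells
  expect_setequal(res$allCells, "t1")
  expect_setequal(res$anyCell, "t1")
  expect_equal(sum(res$byCell$tdna_id == "t1"), 2)

  pc1 <- PeakCollection(list(
    cA = list(CTCF = cover(9000), RAD21 = cover(9000), SMC3 = cover(9000)),
    cB = list(CTCF = cover(9000), RAD21 = cover(9000), SMC3 = gri("chr1", 1, 10))))
  res1 <- cohesinColocalization(td, pc1)
  expect_setequal(res1$anyCell, "t3")
  expect_equal(res1$byCell$cell_line[res1$byCell$tdna_id == "t3"], "cA")
  expect_length(res1$allCells, 0)

  pcBad <- PeakCollection(list(cA = list(CTCF = cover(1000),
                                         RAD21 = cover(1000))))
  expect_error(cohesinColocalization(td, pcBad), "SMC3")
})

test_that("planted triple colocalization is recovered exactly", {
  cfg <- tinyConfig(seed = 37)
  sim <- simulateAll(cfg)
  res <- cohesinColocalization(sim$tdnas, sim$peaks)
  tp <- truthPeaks(sim$truth)
  expect_setequal(res$anyCell, unique(tp$cohesin$tdna_id))
  expect_setequal(res$allCells, tp$cohesinAllCells)
})
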