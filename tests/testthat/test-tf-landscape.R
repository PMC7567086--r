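mkTdnas <- function(starts, strand = "+", chrom = "chr1", len = 72) {
  TDNASet(gri(chrom, starts, starts + len - 1, strand,
              tdna_id = sprintf("t%02d", seq_along(starts))))
}

test_that("countTfs distinguishes unique factors from total events", {
  td <- mkTdnas(1000)
  pc <- onecell(A = gri("chr1", c(990, 1050), c(1010, 1080)),
                B = gri("chr1", 1060, 1200),
                C = gri("chr1", 5000, 5100))
  expect_equal(countTfs(td, pc)[1, 1], 2L)          # A, B
  expect_equal(countTfs(td, pc, "total")[1, 1], 3L) # A twice + B
  # nothing on the locus chromosome
  pc2 <- onecell(A = gri("chr9", 1000, 1100))
  expect_equal(countTfs(td, pc2)[1, 1], 0L)
  expect_equal(countTfs(td, pc2, "total")[1, 1], 0L)
  expect_error(countTfs(td, pc, cells = "nope"), "unknown cell line")
})

test_that("countTfs(unique) matches a brute-force per-base oracle", {
  set.seed(21)
  for (rep_ in 1:40) {
    nl <- sample(2:5, 1); np <- sample(1:20, 1)
    ls <- sample.int(3000, nl) ; td <- mkTdnas(ls)
    tf <- sample(LETTERS[1:4], np, TRUE)
    ps <- sample.int(3200, np); pw <- sample.int(150, np)
    fl <- lapply(split(seq_len(np), tf), function(i)
      gri("chr1", ps[i], ps[i] + pw[i]))
    pc <- PeakCollection(list(cellA = fl))
    got <- countTfs(td, pc)[, 1]
    want <- vapply(seq_len(nl), function(i) {
      lbases <- seq(ls[i], ls[i] + 71)
      sum(vapply(fl, function(g) any(vapply(seq_along(g), function(k)
        length(intersect(lbases, seq(GenomicRanges::start(g)[k],
                                     GenomicRanges::end(g)[k]))) > 0,
        logical(1))), logical(1)))
    }, integer(1))
    expect_equal(unname(got), want)
  }
})

test_that("counts are monotone under adding an overlapping peak", {
  set.seed(22)
  td <- mkTdnas(c(1000, 5000, 9000))
  fl <- list(A = gri("chr1", 980, 1100), B = gri("chr1", 4990, 5050))
  pc <- PeakCollection(list(cellA = fl))
  before <- countTfs(td, pc)
  fl$B <- c(fl$B, gri("chr1", 9000, 9020))
  after <- countTfs(td, PeakCollection(list(cellA = fl)))
  expect_true(all(after >= before))
})

test_that("classifyGroups applies strict-mean and zero rules", {
  m <- rbind(t1 = c(5L, 5L), t2 = c(0L, 0L), t3 = c(5L, 0L))
  colnames(m) <- c("cA", "cB")
  ga <- classifyGroups(m)
  expect_equal(unname(ga@cellMeans), c(10, 5) / 3)
  expect_equal(unname(groupOf(ga, c("t1", "t2", "t3"))), c(1L, 3L, 2L))

  z <- matrix(0L, 4, 2, dimnames = list(paste0("t", 1:4), c("cA", "cB")))
  expect_true(all(groupOf(classifyGroups(z)) == 3L))

  expect_error(classifyGroups(matrix(0L, 0, 2)), "non-empty")
})

test_that("the three groups always partition the locus set", {
  set.seed(23)
  for (rep_ in 1:25) {
    n <- sample(3:60, 1); k <- sample(1:5, 1)
    m <- matrix(rpois(n * k, sample(0:6, 1)), n, k,
                dimnames = list(paste0("t", seq_len(n)), paste0("c", seq_len(k))))
    ga <- classifyGroups(m)
    expect_equal(sum(groupSizes(ga)), n)
    expect_setequal(c(groupMembers(ga, 1), groupMembers(ga, 2),
                      groupMembers(ga, 3)), rownames(m))
    # definitional checks
    for (id in groupMembers(ga, 1))
      expect_true(all(m[id, ] > ga@cellMeans))
    for (id in groupMembers(ga, 3))
      expect_true(all(m[id, ] == 0))
  }
})

test_that("distanceLandscape localizes a covering peak at offset zero", {
  td <- mkTdnas(10000)
  pc <- onecell(A = gri("chr1", 10000, 10071))
  land <- distanceLandscape(td, pc, "cellA", window = 500, bin = 25)
  at0 <- land[land$offset == 0, ]
  expect_equal(c(at0$q25, at0$q50, at0$q75), c(1, 1, 1))
  expect_true(all(land[land$offset != 0, c("q25", "q50", "q75")] == 0))

  empty <- distanceLandscape(td, onecell(A = gri("chr2", 1, 10)), "cellA",
                             window = 500, bin = 25)
  expect_true(all(empty[, c("q25", "q50", "q75")] == 0))
})

test_that("landscape offsets are oriented by the gene strand", {
  plus <- mkTdnas(10000, "+")
  minus <- mkTdnas(10000, "-")
  peakLeft <- onecell(A = gri("chr1", 9500, 9600))  # genomically upstream
  lp <- distanceLandscape(plus, peakLeft, "cellA", window = 1000, bin = 50)
  lm <- distanceLandscape(minus, peakLeft, "cellA", window = 1000, bin = 50)
  expect_true(all(lp$offset[lp$q50 > 0] < 0))
  expect_true(all(lm$offset[lm$q50 > 0] > 0))
  # mirrored profiles
  expect_equal(lp$q50, rev(lm$q50))
})

test_that("landscape quartiles are ordered at every offset", {
  cfg <- tinyConfig(seed = 24)
  sim <- simulateAll(cfg)
  land <- distanceLandscape(sim$tdnas, sim$peaks, "cell01",
                            window = 2000, bin = 50)
  expect_true(all(land$q25 <= land$q50 & land$q50 <= land$q75))
  at0 <- land[land$offset == 0, ]
  expect_true(at0$q75 >= max(land$q75))  # binding concentrates on the body
})

test_that("tfFrequencyByGroup reports planted percentages", {
  td <- mkTdnas(c(1000, 5000, 9000, 13000))
  m <- rbind(t01 = c(3L), t02 = c(4L), t03 = c(0L), t04 = c(5L))
  colnames(m) <- "cellA"
  ga <- classifyGroups(m)  # mean 3: t2,t4 -> G1; t1 -> G2; t3 -> G3
  pc <- onecell(ALL = gri("chr1", c(5000, 13000), c(5071, 13071)),
                HALF = gri("chr1", 5000, 5071),
                NONE = gri("chr1", 40000, 40100))
  f <- tfFrequencyByGroup(td, pc, ga, "cellA", group = 1)
  expect_equal(f$percent[f$factor == "ALL"], 100)
  expect_equal(f$percent[f$factor == "HALF"], 50)
  expect_equal(f$percent[f$factor == "NONE"], 0)
  expect_equal(nrow(f), 3)                       # zero rows are kept
  expect_true(!is.unsorted(rev(f$percent)))      # sorted descending
  m2 <- rbind(t01 = 3L, t02 = 4L); colnames(m2) <- "cellA"
  ga2 <- classifyGroups(m2)   # no Group-3 members
  expect_error(tfFrequencyByGroup(td, pc, ga2, "cellA", group = 3), "empty")
})

test_that("crossCellCorrelation handles identity, negation and degeneracy", {
  set.seed(25)
  a <- rpois(50, 5)
  m <- cbind(cA = a, cB = a)
  rownames(m) <- paste0("t", 1:50)
  expect_equal(crossCellCorrelation(m, "cA", "cB"), 1.0)
  m2 <- cbind(cA = a, cB = as.integer(round(2 * mean(a) - a)))
  rownames(m2) <- rownames(m)
  expect_equal(crossCellCorrelation(m2, "cA", "cB"), -1.0)
  m3 <- cbind(cA = a, cB = rep(3L, 50))
  rownames(m3) <- rownames(m)
  expect_error(crossCellCorrelation(m3, "cA", "cB"), "zero variance")
  expect_error(crossCellCorrelation(m, "cA", "nope"), "lacks")
})

test_that("restricting to shared factors recomputes counts on the intersection", {
  td <- mkTdnas(c(1000, 5000, 9000))
  pc <- PeakCollection(list(
    cA = list(X = gri("chr1", 5000, 5071),
              Y = gri("chr1", c(1000, 9000), c(1071, 9071))),
    cB = list(Y = gri("chr1", c(1010, 9010), c(1030, 9030)),
              Z = gri("chr1", 5000, 5071))))
  # only Y is shared; X and Z would otherwise make the columns differ
  r <- crossCellCorrelation(td, "cA", "cB", peaks = pc, restrictToShared = TRUE)
  expect_equal(r, 1.0)
})

test_that("cell-specific selection uses strict thresholds on both sides", {
  m <- rbind(a = c(21L, 4L), b = c(20L, 4L), c = c(21L, 5L), d = c(30L, 0L))
  colnames(m) <- c("K", "G")
  expect_setequal(cellSpecificTdnas(m, "K", "G"), c("a", "d"))
})
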