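## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately naive (per-base sets, per-window loops) and share no code with
## the package implementations they check.

gri <- function(seqname, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(seqname, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

## small strong PWM (width 6) for fast scanning tests
toyPwm <- function(threshold = 3.0) {
  cons <- c("G", "C", "A", "T", "G", "C")
  m <- matrix(-4, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- 2.5
  PWMotif(m, name = "toy", threshold = threshold)
}

## column-wise reverse-complement symmetric PWM: w[b, j] == w[comp(b), W+1-j]
palindromicPwm <- function(threshold = 0) {
  col1 <- c(A = 1.0, C = -0.5, G = 0.2, T = -1.2)
  col2 <- c(A = -0.3, C = 0.8, G = -1.0, T = 0.4)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- function(cl) stats::setNames(cl[comp], names(cl))
  m <- cbind(col1, col2, flip(col2), flip(col1))
  rownames(m) <- c("A", "C", "G", "T")
  colnames(m) <- NULL
  PWMotif(m, name = "palindrome", threshold = threshold)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompChar <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

## per-base set-intersection overlap oracle
bruteOverlapBp <- function(a, b) {
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b))) return(0L)
  length(intersect(seq(GenomicRanges::start(a), GenomicRanges::end(a)),
                   seq(GenomicRanges::start(b), GenomicRanges::end(b))))
}

## naive two-strand exhaustive PWM scan returning (start, strand, score)
bruteScan <- function(pwm, s, threshold) {
  w <- pwmWidth(pwm)
  out <- list()
  for (st in seq_len(nchar(s) - w + 1)) {
    win <- substr(s, st, st + w - 1)
    for (strand_ in c("p", "n")) {
      k <- if (strand_ == "p") win else revcompChar(win)
      sc <- 0
      ok <- TRUE
      for (j in seq_len(w)) {
        b <- substr(k, j, j)
        if (!b %in% c("A", "C", "G", "T")) { ok <- FALSE; break }
        sc <- sc + pwm@weights[b, j]
      }
      if (ok && sc > threshold)
        out[[length(out) + 1]] <- data.frame(start = st, strand = strand_,
                                             score = sc)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(), strand = character(), score = numeric())
}

## brute-force nearest-border distance: minimum over every border coordinate
## of every merged domain, sign by midpoint containment
bruteBorderDist <- function(mid, domStarts, domEnds) {
  ## merge by sweeping
  o <- order(domStarts)
  ds <- domStarts[o]; de <- domEnds[o]
  ms <- ds[1]; me <- de[1]; S <- c(); E <- c()
  for (k in seq_along(ds)[-1]) {
    if (ds[k] <= me + 1) me <- max(me, de[k])
    else { S <- c(S, ms); E <- c(E, me); ms <- ds[k]; me <- de[k] }
  }
  S <- c(S, ms); E <- c(E, me)
  d <- min(abs(mid - c(S, E)))
  if (any(S <= mid & mid <= E)) d else -d
}

## small fast generator configuration for unit tests
tinyConfig <- function(seed = 42, ...) {
  args <- list(seed = seed, nTdnas = 60L, nCellLines = 3L, nTfsPerCell = 15L,
               genomeLength = 2e7, nCohesin = 4L, nCohesinAllCells = 2L,
               backgroundPeakDensity = 2, dhsBackgroundDensity = 4,
               consBackgroundDensity = 6)
  args <- utils::modifyList(args, list(...))
  do.call(simConfig, args)
}

emptyLoci <- function() {
  gr <- GenomicRanges::GRanges()
  gr$tdna_id <- character(0)
  gr
}

## a PeakCollection built from explicit GRanges, one cell line
onecell <- function(..., cell = "cellA") {
  PeakCollection(stats::setNames(list(list(...)), cell))
}
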