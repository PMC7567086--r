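## Per-tDNA TF census across cell lines, the positional quartile landscape,
## cross-cell-line comparisons and the three-group classifier. Binding is
## always the ">= 1 bp overlap" rule.

#' Count TFs bound to each tDNA in each cell line
#'
#' `unique` mode counts, per locus and cell line, the number of distinct
#' factor names with at least one peak overlapping the locus by >= 1 bp
#' ("unique TFs"); `total` counts (factor, peak) overlap events ("total
#' TFs"). Peaks are assumed pre-filtered by length
#' ([filterPeaksByLength()]).
#'
#' @param tdnas a [TDNASet-class] or `GRanges`.
#' @param peaks a [PeakCollection-class].
#' @param mode `"unique"` or `"total"`.
#' @param cells cell lines to count (default all in `peaks`); unknown names
#'   are an error.
#' @return integer matrix, rows = tdna ids, columns = cell lines.
#' @export
countTfs <- function(tdnas, peaks, mode = c("unique", "total"),
                     cells = cellLines(peaks)) {
  mode <- match.arg(mode)
  gr <- .asLociGRanges(tdnas)
  unknown <- setdiff(cells, cellLines(peaks))
  if (length(unknown))
    stop("unknown cell line(s): ", paste(unknown, collapse = ", "))
  out <- matrix(0L, length(gr), length(cells),
                dimnames = list(gr$tdna_id, cells))
  for (cell in cells) {
    acc <- integer(length(gr))
    for (tf in tfNames(peaks, cell)) {
      p <- peaksOf(peaks, cell, tf)
      if (!length(p)) next
      if (mode == "unique") acc <- acc + as.integer(IRanges::overlapsAny(gr, p))
      else acc <- acc + countOverlaps(gr, p)
    }
    out[, cell] <- acc
  }
  out
}

#' Positional TF-binding landscape around tDNAs
#'
#' For one cell line, counts for every locus and every signed offset bin in
#' `[-window, window]` (strand-oriented: upstream of the gene is negative) the
#' number of distinct TFs with a peak covering at least one base of that bin,
#' then takes the 25th/50th/75th percentiles across loci per bin. Offsets are
#' measured edge-to-edge from the locus: bin 0 is the locus body itself, bin
#' `k > 0` covers gap distances `(k-1)*bin + 1 ... k*bin` downstream, and
#' symmetrically upstream. Percentiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param tdnas a [TDNASet-class] or `GRanges`.
#' @param peaks a [PeakCollection-class].
#' @param cell cell line name.
#' @param window half-width of the profiled region, bp (default 5000).
#' @param bin bin width, bp (default 25).
#' @return `data.frame` with columns `offset` (bin index * bin width), `q25`,
#'   `q50`, `q75`.
#' @export
distanceLandscape <- function(tdnas, peaks, cell, window = 5000L, bin = 25L) {
  stopifnot(window >= bin, bin >= 1)
  gr <- .asLociGRanges(tdnas)
  if (!cell %in% cellLines(peaks)) stop("unknown cell line: ", cell)
  nb <- as.integer(ceiling(window / bin))       # bins each side of the body
  nbins <- 2L * nb + 1L
  nloc <- length(gr)
  ext <- GRanges(seqnames(gr),
                 IRanges(pmax(1L, start(gr) - as.integer(window)),
                         end(gr) + as.integer(window)))
  minus <- as.character(strand(gr)) == "-"
  counts <- matrix(0L, nbins, nloc)
  gapBins <- function(glo, ghi) {          # gap distances >= 1 -> bin indices
    lo <- (glo - 1L) %/% bin + 1L
    hi <- (ghi - 1L) %/% bin + 1L
    c(lo, hi)
  }
  for (tf in tfNames(peaks, cell)) {
    p <- peaksOf(peaks, cell, tf)
    if (!length(p)) next
    hits <- findOverlaps(ext, p)
    if (!length(hits)) next
    touched <- matrix(FALSE, nbins, nloc)
    qh <- queryHits(hits); sh <- subjectHits(hits)
    for (hidx in seq_along(qh)) {
      t <- qh[hidx]
      ps <- start(p)[sh[hidx]]; pe <- end(p)[sh[hidx]]
      ts <- start(gr)[t]; te <- end(gr)[t]
      blo <- integer(0); bhi <- integer(0)
      if (ps <= te && pe >= ts) { blo <- 0L; bhi <- 0L }       # body
      if (ps < ts) {                                           # genomic left
        g1 <- ts - min(pe, ts - 1L); g2 <- ts - max(ps, ts - as.integer(window))
        if (g1 <= g2 && g1 >= 1L) {
          b <- gapBins(g1, g2)
          sgn <- if (minus[t]) 1L else -1L
          blo <- c(blo, min(sgn * b)); bhi <- c(bhi, max(sgn * b))
        }
      }
      if (pe > te) {                                           # genomic right
        g1 <- max(ps, te + 1L) - te; g2 <- min(pe, te + as.integer(window)) - te
        if (g1 <= g2 && g1 >= 1L) {
          b <- gapBins(g1, g2)
          sgn <- if (minus[t]) -1L else 1L
          blo <- c(blo, min(sgn * b)); bhi <- c(bhi, max(sgn * b))
        }
      }
      for (k in seq_along(blo)) {
        lo_ <- max(-nb, blo[k]); hi_ <- min(nb, bhi[k])
        if (lo_ > hi_) next
        touched[(lo_:hi_) + nb + 1L, t] <- TRUE
      }
    }
    counts <- counts + touched
  }
  qs <- apply(counts, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75),
              type = 7, names = FALSE)
  data.frame(offset = (seq_len(nbins) - nb - 1L) * bin,
             q25 = qs[1, ], q50 = qs[2, ], q75 = qs[3, ])
}

#' Classify tDNAs into Groups 1/2/3 by TF binding
#'
#' Per-cell-line mean TF counts are computed over all loci (zeros included).
#' Group 1: count strictly above the mean in every cell line. Group 3: count
#' zero in every cell line. Group 2: everything else. The three groups
#' partition the locus set.
#'
#' @param counts integer matrix from [countTfs()] (rows = loci, columns =
#'   cell lines).
#' @return a [GroupAssignment-class].
#' @examples
#' m <- rbind(t1 = c(5, 5), t2 = c(0, 0), t3 = c(5, 0))
#' colnames(m) <- c("cellA", "cellB")
#' groupOf(classifyGroups(m))   # t1 -> 1, t2 -> 3, t3 -> 2
#' @export
classifyGroups <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("classifyGroups requires a non-empty count matrix")
  if (is.null(rownames(counts)))
    stop("count matrix must have tdna ids as rownames")
  mu <- colMeans(counts)
  above <- sweep(counts, 2, mu, ">")
  g <- rep(2L, nrow(counts))
  g[rowSums(above) == ncol(counts)] <- 1L
  g[rowSums(counts) == 0L] <- 3L
  names(g) <- rownames(counts)
  new("GroupAssignment", groups = g, cellMeans = mu, counts = counts)
}

#' Per-factor binding frequency within one group
#'
#' For one cell line, the percentage of the group's loci overlapped (>= 1 bp)
#' by at least one peak of each factor, sorted in descending order.
#'
#' @param tdnas a [TDNASet-class] or `GRanges`.
#' @param peaks a [PeakCollection-class].
#' @param assignment a [GroupAssignment-class].
#' @param cell cell line name.
#' @param group group label (1, 2 or 3); the group must be non-empty.
#' @return `data.frame` with columns `factor`, `n_bound`, `percent`, all
#'   assayed factors included (0% rows kept).
#' @export
tfFrequencyByGroup <- function(tdnas, peaks, assignment, cell, group = 1L) {
  gr <- .asLociGRanges(tdnas)
  members <- groupMembers(assignment, group)
  if (!length(members)) stop("group ", group, " is empty")
  sub <- gr[gr$tdna_id %in% members]
  tf <- tfNames(peaks, cell)
  nb <- vapply(tf, function(f)
    sum(IRanges::overlapsAny(sub, peaksOf(peaks, cell, f))), integer(1))
  out <- data.frame(factor = tf, n_bound = nb,
                    percent = 100 * nb / length(sub))
  out <- out[order(-out$percent, out$factor), ]
  rownames(out) <- NULL
  out
}

#' Pearson correlation of per-tDNA TF counts between two cell lines
#'
#' With a count matrix, correlates the two named columns. With a locus set and
#' a [PeakCollection-class], counts are computed on the fly;
#' `restrictToShared = TRUE` first intersects the two cell lines' factor-name
#' sets and recomputes counts over the shared factors only (the
#' shared-TF comparison).
#'
#' @param x a count matrix from [countTfs()], or a [TDNASet-class]/`GRanges`.
#' @param cellA,cellB cell line names.
#' @param peaks required when `x` is a locus set.
#' @param restrictToShared restrict to factors assayed in both cell lines.
#' @return Pearson r in `[-1, 1]`.
#' @export
crossCellCorrelation <- function(x, cellA, cellB, peaks = NULL,
                                 restrictToShared = FALSE) {
  if (is.matrix(x)) {
    if (restrictToShared)
      stop("restrictToShared requires the locus set and peaks, not a matrix")
    if (!all(c(cellA, cellB) %in% colnames(x)))
      stop("count matrix lacks requested cell line column(s)")
    a <- x[, cellA]; b <- x[, cellB]
  } else {
    if (is.null(peaks)) stop("peaks required when x is a locus set")
    if (restrictToShared) {
      shared <- intersect(tfNames(peaks, cellA), tfNames(peaks, cellB))
      if (!length(shared)) stop("no shared factors between ", cellA, " and ", cellB)
      sub <- PeakCollection(list(
        a = peaks@peaks[[cellA]][shared],
        b = peaks@peaks[[cellB]][shared]))
      names(sub@peaks) <- c(cellA, cellB)
      m <- countTfs(x, sub)
    } else m <- countTfs(x, peaks, cells = c(cellA, cellB))
    a <- m[, cellA]; b <- m[, cellB]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero variance in ",
         if (stats::sd(a) == 0) cellA else cellB)
  stats::cor(a, b)
}

#' tDNAs bound cell-specifically between two cell lines
#'
#' Loci with strictly more than `hi` TFs in `cellA` and strictly fewer than
#' `lo` TFs in `cellB`.
#'
#' @param counts matrix from [countTfs()].
#' @param cellA,cellB cell line names.
#' @param hi,lo thresholds (defaults 20 and 5); `hi >= lo >= 0`.
#' @return character vector of tdna ids.
#' @export
cellSpecificTdnas <- function(counts, cellA, cellB, hi = 20L, lo = 5L) {
  stopifnot(hi >= lo, lo >= 0)
  if (!all(c(cellA, cellB) %in% colnames(counts)))
    stop("count matrix lacks requested cell line column(s)")
  rownames(counts)[counts[, cellA] > hi & counts[, cellB] < lo]
}
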