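## Motif-hit confirmation against ChIP peaks, tRNA structural-region
## assignment, and CTCF/cohesin triple-colocalization calling.

.hitsToGRanges <- function(hits) {
  if (!all(c("seqnames", "g_start", "g_end") %in% names(hits)))
    stop("hits lack genomic coordinates; scan a TDNASet (not bare sequences)")
  GRanges(hits$seqnames, IRanges(hits$g_start, hits$g_end))
}

.ctcfGRanges <- function(chipPeaks, factorName = "CTCF") {
  if (is(chipPeaks, "PeakCollection")) {
    grl <- lapply(cellLines(chipPeaks), function(cell) {
      if (factorName %in% tfNames(chipPeaks, cell))
        peaksOf(chipPeaks, cell, factorName) else GRanges()
    })
    do.call(c, c(grl, list(GRanges())))
  } else if (is(chipPeaks, "GRanges")) chipPeaks
  else if (is.list(chipPeaks)) do.call(c, c(unname(chipPeaks), list(GRanges())))
  else stop("chipPeaks must be a PeakCollection, GRanges or list of GRanges")
}

#' Confirm motif hits against CTCF ChIP peaks
#'
#' A hit is ChIP-confirmed when its genomic interval overlaps (>= 1 bp) a CTCF
#' peak in at least one supplied cell line. All hits are retained either way.
#' When scanning tDNA loci the motif-overlaps-a-tDNA criterion holds by
#' construction; it is re-checked (against `tdnas`) when supplied, covering
#' scans of wider sequence.
#'
#' @param hits `data.frame` from [scanPwm()] on a [TDNASet-class].
#' @param chipPeaks CTCF peaks: a [PeakCollection-class] (factor `"CTCF"` per
#'   cell line), a `GRanges`, or a list of `GRanges`.
#' @param tdnas optional [TDNASet-class]; adds an `in_tdna` re-check column.
#' @return list with `hits` (input plus `chip_confirmed`, and `in_tdna` when
#'   requested) and `summary` (`n_hits`, `n_loci_with_hits`, `n_confirmed`).
#' @export
confirmHits <- function(hits, chipPeaks, tdnas = NULL) {
  if (nrow(hits) == 0L) {
    hits$chip_confirmed <- logical(0)
    return(list(hits = hits, summary = c(n_hits = 0L, n_loci_with_hits = 0L,
                                         n_confirmed = 0L)))
  }
  hg <- .hitsToGRanges(hits)
  ctcf <- .ctcfGRanges(chipPeaks)
  hits$chip_confirmed <- if (length(ctcf)) IRanges::overlapsAny(hg, ctcf)
                         else rep(FALSE, nrow(hits))
  if (!is.null(tdnas))
    hits$in_tdna <- IRanges::overlapsAny(hg, loci(tdnas))
  list(hits = hits,
       summary = c(n_hits = nrow(hits),
                   n_loci_with_hits = length(unique(hits$tdna_id)),
                   n_confirmed = sum(hits$chip_confirmed)))
}

.REGIONS <- c("5prime-D", "D-anticodon", "anticodon-T", "T-3prime")

#' Assign motif hits to tRNA structural regions
#'
#' Each hit is assigned by the position of its midpoint relative to three
#' landmarks — the midpoints of the D-loop, anticodon-loop and T-loop spans of
#' the locus's segmentation — yielding four regions: 5' terminal to D-loop,
#' D-loop to anticodon loop, anticodon loop to T-loop (which absorbs the
#' variable loop), and T-loop to 3' terminal. A midpoint exactly on a landmark
#' assigns to the downstream (3') region. Hits on loci without a segmentation
#' are labelled `"unassigned"`.
#'
#' @param hits `data.frame` from [scanPwm()] (locus-relative coordinates are
#'   used, so gene orientation is already accounted for).
#' @param tdnas a [TDNASet-class] carrying structural segmentations.
#' @return `hits` with a `structural_region` column added.
#' @export
assignStructuralRegion <- function(hits, tdnas) {
  st <- tdnaStructures(tdnas)
  region <- rep("unassigned", nrow(hits))
  mp <- floor((hits$start + hits$end) / 2)
  for (k in seq_len(nrow(hits))) {
    seg <- st[[hits$tdna_id[k]]]
    if (is.null(seg)) next
    lm <- vapply(c("dloop", "anticodon", "tloop"), function(nm) {
      i <- match(nm, names(seg))
      floor((IRanges::start(seg)[i] + IRanges::end(seg)[i]) / 2)
    }, numeric(1))
    region[k] <- .REGIONS[1L + sum(mp[k] >= lm)]
  }
  hits$structural_region <- region
  hits
}

#' CTCF/cohesin triple colocalization at tDNAs
#'
#' For each locus and each requested cell line, calls colocalization when
#' every required factor (default CTCF, RAD21, SMC3) has at least one peak
#' overlapping the locus by >= 1 bp in that cell line. Reports the per-locus
#' cell lists, the loci colocalized in at least one cell line, and the subset
#' colocalized in all requested cell lines.
#'
#' @param tdnas a [TDNASet-class] or `GRanges`.
#' @param peaks a [PeakCollection-class]; every requested cell line must have
#'   all required factors assayed (error naming the missing factor otherwise).
#' @param required character vector of required factor names.
#' @param cells cell lines to consider (default all).
#' @return list with `byCell` (`data.frame` of `tdna_id`, `cell_line`),
#'   `anyCell` (ids colocalized in >= 1 cell line), `allCells` (ids
#'   colocalized in every requested cell line).
#' @export
cohesinColocalization <- function(tdnas, peaks,
                                  required = c("CTCF", "RAD21", "SMC3"),
                                  cells = cellLines(peaks)) {
  gr <- .asLociGRanges(tdnas)
  for (cell in cells) {
    if (!cell %in% cellLines(peaks)) stop("unknown cell line: ", cell)
    missing_ <- setdiff(required, tfNames(peaks, cell))
    if (length(missing_))
      stop("cell line ", cell, " lacks required factor(s): ",
           paste(missing_, collapse = ", "))
  }
  coloc <- matrix(FALSE, length(gr), length(cells),
                  dimnames = list(gr$tdna_id, cells))
  for (cell in cells) {
    ok <- rep(TRUE, length(gr))
    for (f in required)
      ok <- ok & IRanges::overlapsAny(gr, peaksOf(peaks, cell, f))
    coloc[, cell] <- ok
  }
  idx <- which(coloc, arr.ind = TRUE)
  byCell <- data.frame(tdna_id = rownames(coloc)[idx[, 1]],
                       cell_line = cells[idx[, 2]],
                       stringsAsFactors = FALSE)
  byCell <- byCell[order(byCell$tdna_id, byCell$cell_line), , drop = FALSE]
  rownames(byCell) <- NULL
  list(byCell = byCell,
       anyCell = rownames(coloc)[rowSums(coloc) >= 1L],
       allCells = rownames(coloc)[rowSums(coloc) == length(cells)])
}
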