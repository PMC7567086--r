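## Distance-to-border profiles against TAD/LAD annotations, containment and
## track-overlap fractions. Domains are merged (overlapping or book-ended
## records collapsed) before border extraction: borders of merged blocks are
## the biologically meaningful boundaries. A locus is represented by its
## midpoint, which for a ~72-bp gene against domains of hundreds of kb avoids
## double-counting loci that straddle a border.

.asLociGRanges <- function(x) {
  if (is(x, "TDNASet")) loci(x)
  else if (is(x, "GRanges")) {
    if (is.null(x$tdna_id))
      x$tdna_id <- if (!is.null(x$name)) x$name else
        paste0("locus", seq_along(x))
    x
  } else stop("expected a TDNASet or GRanges")
}

.midpoints <- function(gr) floor((start(gr) + end(gr)) / 2)

#' Signed distance from each locus to its nearest domain border
#'
#' Distance is measured from the locus midpoint to the nearest start or end of
#' the merged domain set, positive when the midpoint lies inside a domain,
#' negative when outside, 0 exactly on a border. Loci on sequences with no
#' domain get `NA` distance and `inside = NA`.
#'
#' @param x a [TDNASet-class] or `GRanges`.
#' @param domains `GRanges` of domain intervals (TADs or LADs).
#' @return `data.frame` with columns `tdna_id`, `distance`, `inside`.
#' @export
nearestBorderDistance <- function(x, domains) {
  gr <- .asLociGRanges(x)
  m <- .midpoints(gr)
  dom <- reduce(domains)
  out <- data.frame(tdna_id = gr$tdna_id, distance = NA_real_, inside = NA,
                    stringsAsFactors = FALSE)
  for (sq in unique(as.character(seqnames(gr)))) {
    di <- which(as.character(seqnames(dom)) == sq)
    qi <- which(as.character(seqnames(gr)) == sq)
    if (!length(di)) next
    ds <- start(dom)[di]; de <- end(dom)[di]
    borders <- sort(c(ds, de))
    for (k in qi) {
      dd <- min(abs(m[k] - borders))
      ins <- any(ds <= m[k] & m[k] <= de)
      out$distance[k] <- if (ins) dd else -dd
      out$inside[k] <- ins
    }
  }
  out
}

#' Histogram of nearest-border distances, stratified by group
#'
#' Bins the signed nearest-border distances of all loci falling within
#' `[-window, window]`; loci farther away (or with no domain on their
#' sequence) are excluded and reported in the `n_excluded` attribute. Negative
#' distances mean outside the domain.
#'
#' @param x a [TDNASet-class] or `GRanges`.
#' @param domains `GRanges` of domains.
#' @param groups optional [GroupAssignment-class]; adds per-group columns.
#' @param window profile half-width, bp (default 500 kb, suited to TADs; use
#'   ~150 kb for LADs).
#' @param bin bin width, bp (default 10 kb; use ~5 kb for LADs).
#' @return `data.frame` with `bin_lo`, `bin_hi`, `bin_mid`, `all`, and (with
#'   `groups`) `group1`, `group2`, `group3` counts.
#' @export
borderProfile <- function(x, domains, groups = NULL,
                          window = 5e5, bin = 1e4) {
  stopifnot(window >= bin, bin > 0)
  nb <- nearestBorderDistance(x, domains)
  keep <- !is.na(nb$distance) & abs(nb$distance) <= window
  breaks <- seq(-window, window, by = bin)
  if (breaks[length(breaks)] < window) breaks <- c(breaks, window)
  cutbin <- function(d) {
    if (!length(d)) return(integer(length(breaks) - 1L))
    tabulate(findInterval(d, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(breaks) - 1L)
  }
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out$all <- cutbin(nb$distance[keep])
  if (!is.null(groups)) {
    g <- groupOf(groups, nb$tdna_id)
    for (k in 1:3)
      out[[paste0("group", k)]] <- cutbin(nb$distance[keep & g == k])
  }
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Fraction of loci contained within any domain
#'
#' A locus counts as contained when its midpoint lies inside a merged domain
#' interval (borders inclusive).
#'
#' @param x a [TDNASet-class] or `GRanges` (typically one group's loci).
#' @param domains `GRanges` of domains.
#' @return list with `percent` (0-100), `inside`, `total`.
#' @examples
#' # 124 of 134 midpoints inside -> 92.5%
#' @export
containmentFraction <- function(x, domains) {
  gr <- .asLociGRanges(x)
  if (!length(gr)) stop("containmentFraction is undefined for an empty locus set")
  m <- .midpoints(gr)
  dom <- reduce(domains)
  mid <- GRanges(seqnames(gr), IRanges(m, m))
  k <- sum(IRanges::overlapsAny(mid, dom))
  list(percent = 100 * k / length(gr), inside = k, total = length(gr))
}

#' Fraction of loci overlapping a track by at least 1 bp
#'
#' @param x a [TDNASet-class] or `GRanges` (typically one group's loci).
#' @param track `GRanges` of track intervals (DHS peaks, conserved elements).
#' @return list with `percent` (0-100), `overlapping`, `total`.
#' @export
trackOverlapFraction <- function(x, track) {
  gr <- .asLociGRanges(x)
  if (!length(gr)) stop("trackOverlapFraction is undefined for an empty locus set")
  k <- sum(IRanges::overlapsAny(gr, track))
  list(percent = 100 * k / length(gr), overlapping = k, total = length(gr))
}
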