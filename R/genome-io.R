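## Interval I/O and primitive interval arithmetic.
##
## Internal convention: all intervals are GRanges (1-based, closed). BED input
## (0-based half-open) is shifted by +1 on the start at read time and shifted
## back on write, so files round-trip bit-exactly. GFF3 is already 1-based
## inclusive and is read verbatim.

.bed_ncols <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)

#' Read a BED file
#'
#' Parses BED3, BED6 or ENCODE narrowPeak. `track`, `browser`, `#` comment and
#' blank lines are tolerated and skipped. Input order is preserved. Coordinates
#' are converted from BED's 0-based half-open convention to the 1-based closed
#' `GRanges` convention.
#'
#' @param path file path.
#' @param dialect one of `"auto"`, `"bed3"`, `"bed6"`, `"narrowPeak"`. With
#'   `"auto"` the dialect is inferred from the column count of the first data
#'   line (3 -> bed3, 4-9 -> bed6, >= 10 -> narrowPeak).
#' @return `GRanges`; `name` and `score` metadata columns are set when present,
#'   and narrowPeak adds `signalValue`, `pValue`, `qValue`, `peak`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", f)
#' readBed(f)   # 1 range, chr1:101-200, width 100
#' @export
readBed <- function(path, dialect = c("auto", "bed3", "bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !(grepl("^(track|browser)\\b", lines) | grepl("^#", lines) |
              !nzchar(trimws(lines)))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(GRanges(tdnaid_empty_mcols()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (dialect == "auto") {
    dialect <- if (nf[1] <= 3L) "bed3" else if (nf[1] <= 9L) "bed6" else "narrowPeak"
  }
  need <- .bed_ncols[[dialect]]
  if (dialect == "bed6") {
    bad <- which(nf < 4L)
  } else bad <- which(nf < need)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": expected at least ",
         if (dialect == "bed6") 4L else need, " fields, found ", nf[bad[1]])
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(s) || anyNA(e)) {
    i <- which(is.na(s) | is.na(e))[1]
    stop("malformed BED line ", lineno[i], ": non-numeric coordinates")
  }
  if (any(e <= s)) {
    i <- which(e <= s)[1]
    stop("invalid interval at line ", lineno[i], ": end (", e[i],
         ") must exceed start (", s[i], ")")
  }
  getcol <- function(k) vapply(fields, function(f)
    if (length(f) >= k) f[[k]] else NA_character_, character(1))
  str_ <- if (dialect != "bed3") {
    v <- getcol(6L); v[is.na(v) | !v %in% c("+", "-")] <- "*"; v
  } else "*"
  gr <- GRanges(chrom, IRanges(s + 1, e), strand = str_)
  if (dialect != "bed3") {
    gr$name <- getcol(4L)
    gr$score <- suppressWarnings(as.numeric(getcol(5L)))
  }
  if (dialect == "narrowPeak") {
    gr$signalValue <- as.numeric(getcol(7L))
    gr$pValue <- as.numeric(getcol(8L))
    gr$qValue <- as.numeric(getcol(9L))
    gr$peak <- as.integer(getcol(10L))
  }
  gr
}

tdnaid_empty_mcols <- function() GRanges()

#' Write a BED file
#'
#' Inverse of [readBed()]: emits 0-based half-open coordinates. Integer fields
#' are written without any reformatting so read/write round-trips are
#' bit-exact.
#'
#' @param gr `GRanges` to write.
#' @param path output file path.
#' @param dialect `"bed3"`, `"bed6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, dialect = c("bed6", "bed3", "narrowPeak")) {
  dialect <- match.arg(dialect)
  chrom <- as.character(seqnames(gr))
  s <- format(start(gr) - 1L, scientific = FALSE, trim = TRUE)
  e <- format(end(gr), scientific = FALSE, trim = TRUE)
  if (dialect == "bed3") {
    out <- paste(chrom, s, e, sep = "\t")
  } else {
    nm <- if (!is.null(gr$name)) gr$name else
      if (!is.null(gr$tdna_id)) gr$tdna_id else rep(".", length(gr))
    sc <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
    sc[is.na(sc)] <- 0
    st <- as.character(strand(gr)); st[st == "*"] <- "."
    out <- paste(chrom, s, e, nm,
                 format(sc, scientific = FALSE, trim = TRUE), st, sep = "\t")
    if (dialect == "narrowPeak") {
      sv <- if (!is.null(gr$signalValue)) gr$signalValue else rep(0, length(gr))
      pv <- if (!is.null(gr$pValue)) gr$pValue else rep(-1, length(gr))
      qv <- if (!is.null(gr$qValue)) gr$qValue else rep(-1, length(gr))
      pk <- if (!is.null(gr$peak)) gr$peak else rep(-1L, length(gr))
      out <- paste(out, sv, pv, qv, pk, sep = "\t")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read intervals from a GFF3 file
#'
#' GFF coordinates are 1-based inclusive and are kept as such in the returned
#' `GRanges`. Comment (`#`) and blank lines are skipped; input order is
#' preserved.
#'
#' @param path file path.
#' @return `GRanges` with `source`, `type`, `score` and `attributes` columns.
#' @export
readGff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    i <- which(nf < 8L)[1]
    stop("malformed GFF line ", lineno[i], ": expected >= 8 fields, found ", nf[i])
  }
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  if (anyNA(s) || anyNA(e)) {
    i <- which(is.na(s) | is.na(e))[1]
    stop("malformed GFF line ", lineno[i], ": non-numeric coordinates")
  }
  if (any(e < s)) {
    i <- which(e < s)[1]
    stop("invalid interval at GFF line ", lineno[i], ": end < start")
  }
  str_ <- vapply(fields, `[[`, character(1), 7L)
  str_[!str_ %in% c("+", "-")] <- "*"
  gr <- GRanges(vapply(fields, `[[`, character(1), 1L), IRanges(s, e),
                strand = str_)
  gr$source <- vapply(fields, `[[`, character(1), 2L)
  gr$type <- vapply(fields, `[[`, character(1), 3L)
  gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 6L)))
  gr$attributes <- vapply(fields, function(f)
    if (length(f) >= 9L) f[[9L]] else ".", character(1))
  gr
}

#' Write intervals to a GFF3 file
#'
#' @param gr `GRanges`; `source`, `type`, `score`, `attributes` columns are
#'   used when present.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGff <- function(gr, path) {
  n <- length(gr)
  src <- if (!is.null(gr$source)) gr$source else rep("tdnascape", n)
  typ <- if (!is.null(gr$type)) gr$type else rep("region", n)
  sc <- if (!is.null(gr$score)) ifelse(is.na(gr$score), ".", gr$score) else rep(".", n)
  st <- as.character(strand(gr)); st[st == "*"] <- "."
  at <- if (!is.null(gr$attributes)) gr$attributes else rep(".", n)
  out <- paste(as.character(seqnames(gr)), src, typ,
               format(start(gr), scientific = FALSE, trim = TRUE),
               format(end(gr), scientific = FALSE, trim = TRUE),
               sc, st, ".", at, sep = "\t")
  writeLines(c("##gff-version 3", out), path)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings that keep names and sequence content intact
#' (write-then-read is the identity).
#'
#' @param path file path.
#' @return `readFasta` returns a `DNAStringSet`.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readDNAStringSet(path)
}

#' @rdname readFasta
#' @param seqs `DNAStringSet` (or coercible) to write.
#' @export
writeFasta <- function(seqs, path) {
  writeXStringSet(as(seqs, "DNAStringSet"), path)
  invisible(path)
}

#' Drop peaks longer than a maximum length
#'
#' ChIP peaks spanning more than `maxLen` bases (default 1 kb) are removed, on
#' the grounds that a single factor is unlikely to occupy a longer footprint
#' and such entries are likely experimental artifacts. The comparison is
#' strict: a peak of exactly `maxLen` bases is retained. Relative order is
#' preserved and the number of removed peaks is reported as an attribute.
#'
#' @param peaks `GRanges`.
#' @param maxLen maximum retained width in bp (default 1000).
#' @return filtered `GRanges` with attribute `removed` = number dropped.
#' @export
filterPeaksByLength <- function(peaks, maxLen = 1000L) {
  stopifnot(maxLen >= 1)
  keep <- width(peaks) <= maxLen
  out <- peaks[keep]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Overlap length of two intervals, in base pairs
#'
#' Returns the number of bases shared by `a` and `b` (0 when they are on
#' different sequences or merely abut). Symmetric. Vectorised over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return integer vector of overlap widths (>= 0).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' overlapBp(a, b)  # 50
#' @export
overlapBp <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  as.integer(ifelse(same, pmax(0L, ov), 0L))
}

#' Signed edge-to-edge distance between an anchor and another interval
#'
#' Zero iff the two intervals overlap by at least 1 bp; otherwise the
#' edge-to-edge gap in bases, negative when `other` lies upstream of the
#' anchor and positive when downstream. With `orientByStrand = TRUE`
#' (default), upstream/downstream follow the anchor's strand, so for a
#' minus-strand anchor an interval to its genomic left is downstream
#' (positive).
#'
#' @param anchor,other `GRanges` of equal length (or length 1, recycled); each
#'   pair must share a sequence name.
#' @param orientByStrand flip the sign for minus-strand anchors.
#' @return integer vector of signed distances.
#' @export
signedDistance <- function(anchor, other, orientByStrand = TRUE) {
  n <- max(length(anchor), length(other))
  if (length(anchor) == 1L) anchor <- rep(anchor, n)
  if (length(other) == 1L) other <- rep(other, n)
  stopifnot(length(anchor) == length(other))
  if (any(as.character(seqnames(anchor)) != as.character(seqnames(other))))
    stop("signedDistance is undefined across different sequences")
  gap_left <- start(anchor) - end(other) - 1L   # other entirely left
  gap_right <- start(other) - end(anchor) - 1L  # other entirely right
  d <- integer(n)
  left <- gap_left >= 0L
  right <- gap_right >= 0L
  d[left] <- -gap_left[left]
  d[right] <- gap_right[right]
  if (orientByStrand) {
    flip <- as.character(strand(anchor)) == "-"
    d[flip] <- -d[flip]
  }
  d
}
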