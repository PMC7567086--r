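## Additive log-odds PWM scoring and exhaustive two-strand scanning.

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.encodeSeq <- function(s) {
  v <- strsplit(toupper(as.character(s)), "", fixed = TRUE)[[1]]
  unname(.BASE_CODE[v])   # NA for ambiguous bases
}

# reverse complement of a PWM: complement the base rows and reverse the columns
.rcWeights <- function(w) {
  rc <- w[c("T", "G", "C", "A"), ncol(w):1, drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  rc
}

# scores of every width-w window over an encoded sequence; windows containing
# an ambiguous base come back NA
.scoreAllWindows <- function(weights, codes) {
  w <- ncol(weights)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + weights[cbind(codes[j:(j + n - 1L)], j)]
  }
  sc
}

#' Score one k-mer against a PWM
#'
#' The score is the sum, over motif positions, of the log-odds weight of the
#' observed base. Windows containing an ambiguous base (anything outside
#' A/C/G/T) are never scored and return `NA`.
#'
#' @param pwm a [PWMotif].
#' @param kmer character or `DNAString` of length `pwmWidth(pwm)`.
#' @return numeric score, or `NA_real_` for an ambiguous k-mer.
#' @examples
#' p <- ctcfToyPwm()
#' scoreWindow(p, consensusSequence(p)) == maxScore(p)
#' @export
scoreWindow <- function(pwm, kmer) {
  codes <- .encodeSeq(kmer)
  if (length(codes) != pwmWidth(pwm))
    stop("k-mer length (", length(codes), ") must equal PWM width (",
         pwmWidth(pwm), ")")
  if (anyNA(codes)) return(NA_real_)
  sum(pwm@weights[cbind(codes, seq_along(codes))])
}

#' Consensus sequence of a PWM
#'
#' Per-column highest-weight base; ties resolve to the first base in A,C,G,T
#' order. Scores exactly `maxScore(pwm)` under [scoreWindow()].
#'
#' @param pwm a [PWMotif].
#' @return character consensus k-mer.
#' @export
consensusSequence <- function(pwm) {
  paste(rownames(pwm@weights)[apply(pwm@weights, 2, which.max)], collapse = "")
}

#' Scan sequences for PWM motif hits on both strands
#'
#' Every window on the forward ("p") strand and every reverse-complemented
#' window ("n" strand) whose score strictly exceeds the threshold is reported;
#' overlapping hits and multiple hits per locus are all kept. An n-strand hit
#' is reported at the forward-coordinate window it occupies, with `matched`
#' giving the sequence as scored (i.e. the reverse complement of the forward
#' window). Windows containing ambiguous bases are skipped.
#'
#' For a [TDNASet], each locus sequence (gene strand) is scanned and hit
#' coordinates are reported both locus-relative (1-based, gene orientation)
#' and genomic (`GRanges` convention, mapped through the locus strand).
#'
#' @param pwm a [PWMotif].
#' @param x a [TDNASet] with sequences, or a named `DNAStringSet` /
#'   character vector.
#' @param threshold score cutoff; hits require score > threshold. Defaults to
#'   the PWM's own threshold.
#' @return `data.frame` with columns `tdna_id`, `start`, `end` (locus-relative,
#'   1-based), `strand` ("p"/"n"), `matched`, `score`, and, for a `TDNASet`
#'   input, `seqnames`, `g_start`, `g_end`. Sequences shorter than the PWM
#'   width yield no hits (with a warning).
#' @export
scanPwm <- function(pwm, x, threshold = NULL) {
  if (is.null(threshold)) threshold <- pwm@threshold
  genomic <- is(x, "TDNASet")
  if (genomic) {
    if (!length(tdnaSequences(x)))
      stop("TDNASet has no sequences; motif scanning requires them")
    seqs <- tdnaSequences(x)
    gr <- loci(x)
  } else {
    seqs <- as(x, "DNAStringSet")
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
  }
  w <- pwmWidth(pwm)
  rcw <- .rcWeights(pwm@weights)
  hits <- vector("list", length(seqs))
  short <- character(0)
  for (i in seq_along(seqs)) {
    sq <- as.character(seqs[[i]])
    if (nchar(sq) < w) { short <- c(short, names(seqs)[i]); next }
    codes <- .encodeSeq(sq)
    fwd <- .scoreAllWindows(pwm@weights, codes)
    rev_ <- .scoreAllWindows(rcw, codes)
    pi_ <- which(!is.na(fwd) & fwd > threshold)
    ni <- which(!is.na(rev_) & rev_ > threshold)
    if (!length(pi_) && !length(ni)) next
    st <- c(pi_, ni)
    strand_ <- rep(c("p", "n"), c(length(pi_), length(ni)))
    matched <- substring(sq, st, st + w - 1L)
    matched[strand_ == "n"] <- as.character(
      reverseComplement(DNAStringSet(matched[strand_ == "n"])))
    hits[[i]] <- data.frame(
      tdna_id = names(seqs)[i], start = st, end = st + w - 1L,
      strand = strand_, matched = matched,
      score = c(fwd[pi_], rev_[ni]), stringsAsFactors = FALSE)
  }
  if (length(short))
    warning(length(short), " sequence(s) shorter than the PWM width were skipped")
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(tdna_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      matched = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (genomic) {
    idx <- match(out$tdna_id, tdnaIds(x))
    ls <- start(gr)[idx]; le <- end(gr)[idx]
    minus <- as.character(strand(gr))[idx] == "-"
    gs <- ifelse(minus, le - out$end + 1L, ls + out$start - 1L)
    ge <- ifelse(minus, le - out$start + 1L, ls + out$end - 1L)
    out$seqnames <- as.character(seqnames(gr))[idx]
    out$g_start <- as.integer(gs)
    out$g_end <- as.integer(ge)
  }
  rownames(out) <- NULL
  out
}

#' Read / write a PWM text file
#'
#' The file format is a plain-text numeric matrix, one row per motif position
#' and four whitespace-separated columns (A, C, G, T). An optional header line
#' `A C G T` and `#` comment lines are tolerated. A 4-row x width layout with
#' base row labels is also accepted.
#'
#' @param path file path.
#' @param name motif name (defaults to the file name).
#' @param threshold score threshold stored on the returned [PWMotif].
#' @return `readPwm` returns a [PWMotif].
#' @export
readPwm <- function(path, name = NULL, threshold = 3.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^[ \t]*A[ \t]+C[ \t]+G[ \t]+T[ \t]*$", lines[1]))
    lines <- lines[-1]
  rows <- lapply(strsplit(trimws(lines), "[ \t]+"), function(f) {
    lab <- NULL
    if (f[1] %in% c("A", "C", "G", "T")) { lab <- f[1]; f <- f[-1] }
    list(lab = lab, x = suppressWarnings(as.numeric(f)))
  })
  if (any(vapply(rows, function(r) anyNA(r$x), logical(1))))
    stop("non-numeric value in PWM file: ", path)
  labs <- unlist(lapply(rows, `[[`, "lab"))
  m <- do.call(rbind, lapply(rows, `[[`, "x"))
  if (!is.null(labs) && length(labs) == 4L && setequal(labs, c("A", "C", "G", "T"))) {
    rownames(m) <- labs
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  } else {
    if (ncol(m) != 4L)
      stop("PWM file must have 4 columns (A, C, G, T); found ", ncol(m))
    m <- t(m)
    rownames(m) <- c("A", "C", "G", "T")
  }
  PWMotif(m, name = if (is.null(name)) basename(path) else name,
          threshold = threshold)
}

#' @rdname readPwm
#' @param pwm a [PWMotif] to write (width x 4 layout, header `A C G T`).
#' @export
writePwm <- function(pwm, path) {
  m <- t(pwm@weights)
  lines <- c("A\tC\tG\tT",
             apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Synthetic CTCF-like toy PWM
#'
#' A 14-position log-odds matrix shipped with the package
#' (`inst/extdata/ctcf_like_synthetic_pwm.txt`). It is a synthetic stand-in
#' with a CTCF-flavoured GC-rich consensus, built so that its consensus scores
#' far above the default threshold of 3.0 while random 72-bp sequences almost
#' never reach it; it is used by the simulator and the test fixtures.
#'
#' @param threshold score threshold (default 3.0).
#' @return a [PWMotif].
#' @export
ctcfToyPwm <- function(threshold = 3.0) {
  readPwm(system.file("extdata", "ctcf_like_synthetic_pwm.txt",
                      package = "tdnascape"),
          name = "CTCF_like_synthetic", threshold = threshold)
}
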