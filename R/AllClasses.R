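#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps countOverlaps reduce resize shift
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits metadata metadata<-
#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet
NULL

#' A set of tRNA gene loci
#'
#' Container for tDNA loci: genomic coordinates, GtRNAdb-style identifiers,
#' optional gene-strand sequences, and optional structural segmentations of the
#' mature-tRNA fold (acceptor stems, D-loop, anticodon loop, variable loop,
#' T-loop) expressed in locus-relative, gene-orientation coordinates.
#'
#' @slot ranges `GRanges` of the loci; `mcols()$tdna_id` holds unique ids.
#' @slot sequences `DNAStringSet` of gene-strand sequences (possibly empty);
#'   when present, names match `tdna_id` and widths match locus widths.
#' @slot structures named `list` of `IRanges` (one per locus, possibly empty);
#'   each element has ranges named `acceptor5`, `dloop`, `anticodon`,
#'   `variable`, `tloop`, `acceptor3`, ordered 5' to 3' along the gene,
#'   non-overlapping, within `[1, locus width]`.
#'
#' @seealso [TDNASet()] for construction, [tdnaIds()], [tdnaSequences()],
#'   [tdnaStructures()], [loci()] for access.
#' @export
setClass("TDNASet",
  slots = c(ranges = "GRanges", sequences = "DNAStringSet", structures = "list")
)

setValidity("TDNASet", function(object) {
  msgs <- character()
  ids <- object@ranges$tdna_id
  if (is.null(ids)) {
    msgs <- c(msgs, "ranges must carry a 'tdna_id' metadata column")
  } else {
    if (anyDuplicated(ids)) msgs <- c(msgs, "tdna_id values must be unique")
    if (anyNA(ids)) msgs <- c(msgs, "tdna_id values must not be NA")
  }
  if (length(object@sequences)) {
    if (length(object@sequences) != length(object@ranges))
      msgs <- c(msgs, "sequences must be empty or one per locus")
    else if (!is.null(ids) && !identical(names(object@sequences), as.character(ids)))
      msgs <- c(msgs, "names(sequences) must equal tdna_id")
    else if (any(Biostrings::width(object@sequences) != width(object@ranges)))
      msgs <- c(msgs, "sequence lengths must equal locus widths")
  }
  if (length(object@structures)) {
    if (is.null(names(object@structures)) ||
        !all(names(object@structures) %in% as.character(ids)))
      msgs <- c(msgs, "structures must be named by tdna_id")
    bad <- vapply(names(object@structures), function(id) {
      seg <- object@structures[[id]]
      w <- width(object@ranges)[match(id, ids)]
      !is(seg, "IRanges") ||
        any(IRanges::start(seg) < 1L) || any(IRanges::end(seg) > w) ||
        is.unsorted(IRanges::start(seg), strictly = TRUE) ||
        any(IRanges::start(seg)[-1] <= IRanges::end(seg)[-length(seg)])
    }, logical(1))
    if (any(bad))
      msgs <- c(msgs, paste0("invalid segmentation for: ",
                             paste(names(object@structures)[bad], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TDNASet
#'
#' @param ranges `GRanges` of loci. Ids are taken from `tdna_id` (or `name`)
#'   metadata column, or from `names(ranges)`.
#' @param sequences optional `DNAStringSet` of gene-strand locus sequences.
#' @param structures optional named list of `IRanges` segmentations
#'   (see [canonicalSegmentation()]).
#' @return a `TDNASet`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1072),
#'                              strand = "+", tdna_id = "tRNA-Ala-AGC-1-1")
#' TDNASet(gr)
#' @export
TDNASet <- function(ranges, sequences = NULL, structures = NULL) {
  if (is.null(ranges$tdna_id)) {
    if (!is.null(ranges$name)) ranges$tdna_id <- ranges$name
    else if (!is.null(names(ranges))) ranges$tdna_id <- names(ranges)
    else stop("cannot determine tdna_id: supply a 'tdna_id' or 'name' column")
  }
  ranges$tdna_id <- as.character(ranges$tdna_id)
  if (is.null(sequences)) sequences <- DNAStringSet()
  if (length(sequences) && is.null(names(sequences)))
    names(sequences) <- ranges$tdna_id
  if (is.null(structures)) structures <- list()
  new("TDNASet", ranges = ranges, sequences = sequences,
      structures = structures)
}

#' A collection of ChIP peaks, organised by cell line and factor
#'
#' Nested mapping cell line -> factor name -> `GRanges` of peak intervals,
#' the shape in which ENCODE-style multi-cell, multi-TF peak sets are consumed
#' by the census and colocalization operations.
#'
#' @slot peaks named list (cell line) of named lists (factor) of `GRanges`.
#' @seealso [PeakCollection()], [cellLines()], [tfNames()], [peaksOf()]
#' @export
setClass("PeakCollection", slots = c(peaks = "list"))

setValidity("PeakCollection", function(object) {
  msgs <- character()
  p <- object@peaks
  if (length(p)) {
    if (is.null(names(p)) || anyDuplicated(names(p)) || any(names(p) == ""))
      msgs <- c(msgs, "cell line names must be unique and non-empty")
    for (cell in names(p)) {
      fl <- p[[cell]]
      if (!is.list(fl)) { msgs <- c(msgs, paste0(cell, ": not a list")); next }
      if (length(fl) && (is.null(names(fl)) || anyDuplicated(names(fl))))
        msgs <- c(msgs, paste0(cell, ": factor names must be unique"))
      ok <- vapply(fl, is, logical(1), class2 = "GRanges")
      if (!all(ok)) msgs <- c(msgs, paste0(cell, ": peaks must be GRanges"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PeakCollection
#'
#' @param peaks named list (cell line) of named lists (factor) of `GRanges`.
#' @return a `PeakCollection`.
#' @export
PeakCollection <- function(peaks = list()) new("PeakCollection", peaks = peaks)

#' A position weight matrix with a score threshold
#'
#' Additive log-odds matrix over A/C/G/T. A window's score is the sum over
#' positions of the weight of the observed base; candidate motifs are reported
#' when the score strictly exceeds `threshold`.
#'
#' @slot weights numeric matrix, 4 rows named A,C,G,T, one column per position.
#' @slot name character scalar.
#' @slot threshold numeric scalar; hits require score > threshold (default 3.0).
#' @seealso [PWMotif()], [scoreWindow()], [scanPwm()], [maxScore()]
#' @export
setClass("PWMotif",
  slots = c(weights = "matrix", name = "character", threshold = "numeric"))

setValidity("PWMotif", function(object) {
  w <- object@weights
  msgs <- character()
  if (!is.numeric(w) || nrow(w) != 4L || ncol(w) < 1L)
    msgs <- c(msgs, "weights must be a numeric 4 x width matrix")
  else {
    if (!identical(rownames(w), c("A", "C", "G", "T")))
      msgs <- c(msgs, "rownames(weights) must be A, C, G, T")
    if (any(!is.finite(w)))
      msgs <- c(msgs, "all weights must be finite")
  }
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msgs <- c(msgs, "threshold must be a finite scalar")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PWMotif
#'
#' @param weights 4 x width numeric matrix with rownames A, C, G, T.
#' @param name motif name.
#' @param threshold score threshold; hits must score strictly above it.
#' @return a `PWMotif`.
#' @export
PWMotif <- function(weights, name = "pwm", threshold = 3.0) {
  new("PWMotif", weights = weights, name = name, threshold = threshold)
}

#' Three-group classification of tDNA loci by TF binding
#'
#' Result of [classifyGroups()]: each locus is labelled Group 1 (bound by more
#' than the per-cell-line average number of TFs in every cell line), Group 3
#' (bound by no TF in any cell line) or Group 2 (the rest), together with the
#' per-cell-line mean counts used as thresholds and the count matrix itself.
#'
#' @slot groups named integer vector in {1,2,3}, names = tdna ids.
#' @slot cellMeans named numeric vector of per-cell-line mean TF counts.
#' @slot counts the TF count matrix the classification was derived from.
#' @seealso [classifyGroups()], [groupOf()], [groupSizes()], [groupMembers()]
#' @export
setClass("GroupAssignment",
  slots = c(groups = "integer", cellMeans = "numeric", counts = "matrix"))

setValidity("GroupAssignment", function(object) {
  msgs <- character()
  if (!all(object@groups %in% 1:3)) msgs <- c(msgs, "groups must be in {1,2,3}")
  if (is.null(names(object@groups))) msgs <- c(msgs, "groups must be named")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TDNASet", function(object) {
  cat("TDNASet with", length(object@ranges), "loci on",
      length(unique(as.character(seqnames(object@ranges)))), "sequence(s)\n")
  cat("  sequences:", if (length(object@sequences)) "present" else "absent",
      " structures:", if (length(object@structures)) "present" else "absent", "\n")
})

setMethod("show", "PeakCollection", function(object) {
  cells <- names(object@peaks)
  cat("PeakCollection:", length(cells), "cell line(s)\n")
  for (cell in cells) {
    n <- sum(vapply(object@peaks[[cell]], length, integer(1)))
    cat("  ", cell, ": ", length(object@peaks[[cell]]), " factor(s), ",
        n, " peak(s)\n", sep = "")
  }
})

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif '", object@name, "': width ", ncol(object@weights),
      ", threshold ", object@threshold,
      ", max score ", round(sum(apply(object@weights, 2, max)), 4), "\n", sep = "")
})

setMethod("show", "GroupAssignment", function(object) {
  sz <- tabulate(object@groups, nbins = 3L)
  cat("GroupAssignment over", length(object@groups), "tDNAs:",
      "Group 1 =", sz[1], "| Group 2 =", sz[2], "| Group 3 =", sz[3], "\n")
  cat("  per-cell-line mean TF counts:",
      paste(names(object@cellMeans),
            sprintf("%.2f", object@cellMeans), collapse = ", "), "\n")
})

setMethod("length", "TDNASet", function(x) length(x@ranges))

setMethod("[", "TDNASet", function(x, i, j, ..., drop = TRUE) {
  r <- x@ranges[i]
  s <- if (length(x@sequences)) x@sequences[r$tdna_id] else x@sequences
  st <- if (length(x@structures))
    x@structures[intersect(r$tdna_id, names(x@structures))] else x@structures
  new("TDNASet", ranges = r, sequences = s, structures = st)
})
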