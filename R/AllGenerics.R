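#' @rdname TDNASet-class
#' @param x a `TDNASet`.
#' @export
setGeneric("tdnaIds", function(x) standardGeneric("tdnaIds"))

#' @rdname TDNASet-class
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname TDNASet-class
#' @export
setGeneric("tdnaSequences", function(x) standardGeneric("tdnaSequences"))

#' @rdname TDNASet-class
#' @export
setGeneric("tdnaStructures", function(x) standardGeneric("tdnaStructures"))

#' @rdname PeakCollection-class
#' @param x a `PeakCollection`.
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @rdname PeakCollection-class
#' @param cell cell line name.
#' @export
setGeneric("tfNames", function(x, cell) standardGeneric("tfNames"))

#' @rdname PeakCollection-class
#' @param tf factor name.
#' @export
setGeneric("peaksOf", function(x, cell, tf) standardGeneric("peaksOf"))

#' @rdname PWMotif-class
#' @param x a `PWMotif`.
#' @export
setGeneric("maxScore", function(x) standardGeneric("maxScore"))

#' @rdname PWMotif-class
#' @export
setGeneric("pwmWidth", function(x) standardGeneric("pwmWidth"))

#' @rdname GroupAssignment-class
#' @param x a `GroupAssignment`.
#' @export
setGeneric("groupOf", function(x, ids) standardGeneric("groupOf"))

#' @rdname GroupAssignment-class
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname GroupAssignment-class
#' @param group group label, 1, 2 or 3.
#' @export
setGeneric("groupMembers", function(x, group) standardGeneric("groupMembers"))

setMethod("tdnaIds", "TDNASet", function(x) as.character(x@ranges$tdna_id))
setMethod("loci", "TDNASet", function(x) x@ranges)
setMethod("tdnaSequences", "TDNASet", function(x) x@sequences)
setMethod("tdnaStructures", "TDNASet", function(x) x@structures)

setMethod("cellLines", "PeakCollection", function(x) names(x@peaks))
setMethod("tfNames", "PeakCollection", function(x, cell) {
  if (!cell %in% names(x@peaks)) stop("unknown cell line: ", cell)
  names(x@peaks[[cell]])
})
setMethod("peaksOf", "PeakCollection", function(x, cell, tf) {
  if (!cell %in% names(x@peaks)) stop("unknown cell line: ", cell)
  fl <- x@peaks[[cell]]
  if (!tf %in% names(fl)) stop("unknown factor '", tf, "' in cell line ", cell)
  fl[[tf]]
})

setMethod("maxScore", "PWMotif", function(x) sum(apply(x@weights, 2, max)))
setMethod("pwmWidth", "PWMotif", function(x) ncol(x@weights))

setMethod("groupOf", "GroupAssignment", function(x, ids) {
  if (missing(ids)) return(x@groups)
  out <- x@groups[ids]
  if (anyNA(out)) stop("unknown tdna id(s): ",
                       paste(ids[is.na(out)], collapse = ", "))
  out
})
setMethod("groupSizes", "GroupAssignment", function(x) {
  sz <- tabulate(x@groups, nbins = 3L)
  names(sz) <- c("1", "2", "3")
  sz
})
setMethod("groupMembers", "GroupAssignment", function(x, group) {
  names(x@groups)[x@groups == as.integer(group)]
})
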