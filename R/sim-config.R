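#' Simulation configuration
#'
#' All parameters of the synthetic-data generator. The defaults describe the
#' study conditions the pipeline is validated under: 489 loci of 72 bp on one
#' 100-Mb synthetic chromosome, six cell lines with 60 assayed TFs each,
#' planted group fractions 134/249/106, ChIP peak lengths capped at 1 kb, a
#' 26% motif-plant fraction (129/489), a 13.6% ChIP-confirmation fraction
#' (20/147), 17 cohesin-colocalized loci (7 in all cell lines), DHS and
#' conserved-element fractions of 0.99 (Group 1) and 0.30 (Group 3), and LAD
#' border offsets drawn from a mixture of uniform 0-30 kb and a point mass at
#' 65 kb outside the domain.
#'
#' Binding strength is modelled with a per-locus propensity theta shared
#' across cell lines (uniform on rate +/- spread within each group) and, for
#' Group 2, a per-locus bound-probability q (Beta with mean
#' `group2CellSparsity` and concentration `group2SparsityShape`), resampled so
#' every Group-2 locus is bound in at least one and unbound in at least one
#' cell line. This shared propensity is what produces the high cross-cell-line
#' correlation of per-locus TF counts seen in real data.
#'
#' @slot seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @slot nTdnas,nCellLines,nTfsPerCell counts.
#' @slot genomeLength synthetic chromosome length, bp.
#' @slot chromName synthetic chromosome name.
#' @slot groupFractions length-3 proportions of Groups 1/2/3 (sum to 1).
#' @slot group1TfRate,group1TfSpread mean/half-range of the Group-1 per-locus
#'   fraction of TFs bound per cell line.
#' @slot group2TfRate,group2TfSpread same for Group-2 loci in their bound cells.
#' @slot group2CellSparsity mean probability that a Group-2 locus is bound in a
#'   given cell line.
#' @slot group2SparsityShape Beta concentration (a+b) of the per-locus bound
#'   probability; values < 1 give a U-shaped (locus-consistent) pattern.
#' @slot backgroundPeakDensity background ChIP peaks per Mb per TF.
#' @slot peakLenRange min/max peak length, bp (max must be <= 1000 to satisfy
#'   the ingest filter).
#' @slot tdnaLength locus length, bp (default 72).
#' @slot minLocusGap minimum gap between loci, bp; must exceed
#'   `guardBand + peakLenRange[2]` so planted peaks never reach a neighbour's
#'   guard band.
#' @slot guardBand half-width of the exclusion zone around Group-3 loci within
#'   which background peaks are rejected, bp.
#' @slot motifPlantFraction proportion of loci receiving a planted PWM
#'   consensus.
#' @slot ctcfConfirmFraction proportion of motif-planted loci that also receive
#'   an overlapping CTCF ChIP peak.
#' @slot nCohesin,nCohesinAllCells number of loci with planted
#'   CTCF+RAD21+SMC3 triple colocalization, and how many of those are planted
#'   in every cell line.
#' @slot tadNearFraction,tadNearWindow fraction of Group-1 loci anchored near a
#'   TAD border, and the offset window (bp) they are placed within.
#' @slot tadLenRange min/max TAD length, bp.
#' @slot ladNearFraction fraction of Group-1 loci anchored just outside a LAD.
#' @slot ladUniformMax,ladFarOffset,ladFarProb LAD border offsets are drawn
#'   uniformly on (0, `ladUniformMax`) with probability `1 - ladFarProb`, else
#'   placed exactly at `ladFarOffset` outside the LAD.
#' @slot ladLenRange min/max LAD length, bp.
#' @slot dhsFractions,consFractions per-group (1,2,3) probabilities that a
#'   locus carries a DHS (per cell line) or a conserved element.
#' @slot dhsBackgroundDensity,consBackgroundDensity background intervals per Mb.
#' @seealso [simConfig()], [simulateAll()]
#' @export
setClass("SimConfig", slots = c(
  seed = "integer", nTdnas = "integer", nCellLines = "integer",
  nTfsPerCell = "integer", genomeLength = "numeric", chromName = "character",
  groupFractions = "numeric",
  group1TfRate = "numeric", group1TfSpread = "numeric",
  group2TfRate = "numeric", group2TfSpread = "numeric",
  group2CellSparsity = "numeric", group2SparsityShape = "numeric",
  backgroundPeakDensity = "numeric", peakLenRange = "numeric",
  tdnaLength = "integer", minLocusGap = "numeric", guardBand = "numeric",
  motifPlantFraction = "numeric", ctcfConfirmFraction = "numeric",
  nCohesin = "integer", nCohesinAllCells = "integer",
  tadNearFraction = "numeric", tadNearWindow = "numeric",
  tadLenRange = "numeric",
  ladNearFraction = "numeric", ladUniformMax = "numeric",
  ladFarOffset = "numeric", ladFarProb = "numeric", ladLenRange = "numeric",
  dhsFractions = "numeric", consFractions = "numeric",
  dhsBackgroundDensity = "numeric", consBackgroundDensity = "numeric"
))

setValidity("SimConfig", function(object) {
  msgs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  chk(object@nTdnas >= 1L && object@nCellLines >= 1L && object@nTfsPerCell >= 1L,
      "counts must be >= 1")
  chk(length(object@groupFractions) == 3L &&
        all(object@groupFractions >= 0) &&
        abs(sum(object@groupFractions) - 1) < 1e-8,
      "groupFractions must be three proportions summing to 1")
  for (nm in c("group1TfRate", "group2TfRate", "group2CellSparsity",
               "motifPlantFraction", "ctcfConfirmFraction",
               "tadNearFraction", "ladNearFraction", "ladFarProb"))
    chk(slot(object, nm) >= 0 && slot(object, nm) <= 1,
        paste(nm, "must be in [0,1]"))
  chk(all(object@dhsFractions >= 0 & object@dhsFractions <= 1) &&
        length(object@dhsFractions) == 3L, "dhsFractions must be 3 proportions")
  chk(all(object@consFractions >= 0 & object@consFractions <= 1) &&
        length(object@consFractions) == 3L, "consFractions must be 3 proportions")
  chk(length(object@peakLenRange) == 2L && object@peakLenRange[1] >= 1 &&
        diff(object@peakLenRange) >= 0, "peakLenRange must be an increasing pair")
  chk(object@minLocusGap > object@guardBand + object@peakLenRange[2],
      "minLocusGap must exceed guardBand + max peak length")
  chk(object@nCohesinAllCells <= object@nCohesin,
      "nCohesinAllCells cannot exceed nCohesin")
  chk(object@tdnaLength >= 30L, "tdnaLength must be >= 30")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed RNG seed (integer).
#' @param nTdnas,nCellLines,nTfsPerCell,genomeLength,chromName,groupFractions,group1TfRate,group1TfSpread,group2TfRate,group2TfSpread,group2CellSparsity,group2SparsityShape,backgroundPeakDensity,peakLenRange,tdnaLength,minLocusGap,guardBand,motifPlantFraction,ctcfConfirmFraction,nCohesin,nCohesinAllCells,tadNearFraction,tadNearWindow,tadLenRange,ladNearFraction,ladUniformMax,ladFarOffset,ladFarProb,ladLenRange,dhsFractions,consFractions,dhsBackgroundDensity,consBackgroundDensity
#'   see [SimConfig-class] for meanings and defaults.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 7, nTdnas = 50, nCellLines = 3)
#' @export
simConfig <- function(seed = 1L,
                      nTdnas = 489L,
                      nCellLines = 6L,
                      nTfsPerCell = 60L,
                      genomeLength = 1e8,
                      chromName = "chrS",
                      groupFractions = c(134, 249, 106) / 489,
                      group1TfRate = 0.75, group1TfSpread = 0.20,
                      group2TfRate = 0.50, group2TfSpread = 0.20,
                      group2CellSparsity = 0.40, group2SparsityShape = 0.75,
                      backgroundPeakDensity = 4,
                      peakLenRange = c(150, 1000),
                      tdnaLength = 72L,
                      minLocusGap = 3000,
                      guardBand = 1000,
                      motifPlantFraction = 129 / 489,
                      ctcfConfirmFraction = 20 / 147,
                      nCohesin = 17L, nCohesinAllCells = 7L,
                      tadNearFraction = 0.7, tadNearWindow = 5e4,
                      tadLenRange = c(3e5, 8e5),
                      ladNearFraction = 0.7, ladUniformMax = 3e4,
                      ladFarOffset = 6.5e4, ladFarProb = 0.5,
                      ladLenRange = c(5e5, 1.5e6),
                      dhsFractions = c(0.99, 0.60, 0.30),
                      consFractions = c(0.99, 0.60, 0.30),
                      dhsBackgroundDensity = 10,
                      consBackgroundDensity = 20) {
  new("SimConfig",
      seed = as.integer(seed), nTdnas = as.integer(nTdnas),
      nCellLines = as.integer(nCellLines),
      nTfsPerCell = as.integer(nTfsPerCell),
      genomeLength = genomeLength, chromName = chromName,
      groupFractions = groupFractions,
      group1TfRate = group1TfRate, group1TfSpread = group1TfSpread,
      group2TfRate = group2TfRate, group2TfSpread = group2TfSpread,
      group2CellSparsity = group2CellSparsity,
      group2SparsityShape = group2SparsityShape,
      backgroundPeakDensity = backgroundPeakDensity,
      peakLenRange = peakLenRange, tdnaLength = as.integer(tdnaLength),
      minLocusGap = minLocusGap, guardBand = guardBand,
      motifPlantFraction = motifPlantFraction,
      ctcfConfirmFraction = ctcfConfirmFraction,
      nCohesin = as.integer(nCohesin),
      nCohesinAllCells = as.integer(nCohesinAllCells),
      tadNearFraction = tadNearFraction, tadNearWindow = tadNearWindow,
      tadLenRange = tadLenRange,
      ladNearFraction = ladNearFraction, ladUniformMax = ladUniformMax,
      ladFarOffset = ladFarOffset, ladFarProb = ladFarProb,
      ladLenRange = ladLenRange,
      dhsFractions = dhsFractions, consFractions = consFractions,
      dhsBackgroundDensity = dhsBackgroundDensity,
      consBackgroundDensity = consBackgroundDensity)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|", object@nTdnas, "tDNAs x",
      object@nCellLines, "cell lines x", object@nTfsPerCell, "TFs on",
      object@chromName, sprintf("(%.0f Mb)\n", object@genomeLength / 1e6))
  cat("  group fractions:",
      paste(sprintf("%.3f", object@groupFractions), collapse = " / "), "\n")
})

.SIMCONFIG_SLOTS <- c(
  "seed", "nTdnas", "nCellLines", "nTfsPerCell", "genomeLength", "chromName",
  "groupFractions", "group1TfRate", "group1TfSpread", "group2TfRate",
  "group2TfSpread", "group2CellSparsity", "group2SparsityShape",
  "backgroundPeakDensity", "peakLenRange", "tdnaLength", "minLocusGap",
  "guardBand", "motifPlantFraction", "ctcfConfirmFraction", "nCohesin",
  "nCohesinAllCells", "tadNearFraction", "tadNearWindow", "tadLenRange",
  "ladNearFraction", "ladUniformMax", "ladFarOffset", "ladFarProb",
  "ladLenRange", "dhsFractions", "consFractions", "dhsBackgroundDensity",
  "consBackgroundDensity")

#' Read / write a simulation configuration file
#'
#' Configurations round-trip losslessly through a structured YAML file, one
#' key per parameter.
#'
#' @param path file path.
#' @return `readSimConfig` returns a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .SIMCONFIG_SLOTS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(simConfig, vals)
}

#' @rdname readSimConfig
#' @param config a [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
  vals <- lapply(.SIMCONFIG_SLOTS, function(nm) slot(config, nm))
  names(vals) <- .SIMCONFIG_SLOTS
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' Ground truth planted by the synthetic-data generator
#'
#' Each generator stage records what it planted, so downstream recovery can be
#' verified exactly. Built incrementally: [simulateTdnas()] fills `labels` and
#' `motifs`, [simulatePeaks()] fills `peaks`, [simulateDomains()] fills
#' `domains`, [simulateTracks()] fills `tracks`.
#'
#' @slot labels named integer vector, planted group label per locus.
#' @slot motifs data.frame of planted PWM matches: `tdna_id`, `start`
#'   (locus-relative, 1-based), `strand` ("p"/"n"), `width`.
#' @slot peaks list: `theta` (per-locus binding propensity), `q` (Group-2
#'   bound probability), `boundCells` (locus x cell logical), `cohesin`
#'   (data.frame `tdna_id`, `cell_line`), `cohesinAllCells` (ids),
#'   `ctcfConfirmed` (ids of motif loci given a CTCF peak).
#' @slot domains list: realized signed distances `tadDistance`, `ladDistance`
#'   (named, positive = inside), planted offsets `tadPlanted`, `ladPlanted`
#'   (named by anchored locus).
#' @slot tracks list: `dhs` (locus x cell logical), `conserved` (named
#'   logical).
#' @export
setClass("GroundTruth", slots = c(
  labels = "integer", motifs = "data.frame", peaks = "list",
  domains = "list", tracks = "list"))

setMethod("show", "GroundTruth", function(object) {
  sz <- tabulate(object@labels, nbins = 3L)
  cat("GroundTruth:", length(object@labels), "loci (planted groups",
      paste(sz, collapse = "/"), ");",
      nrow(object@motifs), "planted motif(s);",
      "peaks:", if (length(object@peaks)) "set" else "unset", "|",
      "domains:", if (length(object@domains)) "set" else "unset", "|",
      "tracks:", if (length(object@tracks)) "set" else "unset", "\n")
})

#' @rdname GroundTruth-class
#' @param x a `GroundTruth`.
#' @export
truthLabels <- function(x) x@labels

#' @rdname GroundTruth-class
#' @export
truthMotifs <- function(x) x@motifs

#' @rdname GroundTruth-class
#' @export
truthPeaks <- function(x) x@peaks

#' @rdname GroundTruth-class
#' @export
truthDomains <- function(x) x@domains

#' @rdname GroundTruth-class
#' @export
truthTracks <- function(x) x@tracks
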