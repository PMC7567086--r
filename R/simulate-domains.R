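## Domain (TAD/LAD) and track (DHS/conservation) simulation.

#' Simulate TAD and LAD annotations with controlled tDNA-border placement
#'
#' TADs are built as non-overlapping intervals with gaps: a `tadNearFraction`
#' subset of Group-1 loci act as anchors, each placed a uniform 0 to
#' `tadNearWindow` bp inside one border of its own TAD; filler TADs tile the
#' remaining chromosome. LADs are a sparser tiling; a `ladNearFraction` subset
#' of Group-1 loci is placed just outside a LAD border at an offset drawn from
#' the configured mixture (uniform 0-`ladUniformMax`, or exactly
#' `ladFarOffset`, with probability `ladFarProb` for the latter). Every
#' locus's realized signed distance to its nearest border (computed from the
#' emitted intervals, positive = inside) is recorded in the truth, alongside
#' the planted anchor offsets.
#'
#' @param tdnas a [TDNASet-class].
#' @param truth the matching [GroundTruth-class] (labels required).
#' @param config the [SimConfig-class].
#' @return list with `tads` (`GRanges`), `lads` (`GRanges`) and updated
#'   `truth`.
#' @export
simulateDomains <- function(tdnas, truth, config) {
  set.seed(.stageSeed(config, 202L))
  gr <- loci(tdnas)
  ids <- tdnaIds(tdnas)
  labels <- truthLabels(truth)[ids]
  mids <- as.numeric(floor((start(gr) + end(gr)) / 2))
  names(mids) <- ids
  G <- config@genomeLength
  g1ids <- ids[labels == 1L]

  ## ---- TADs ----
  nAnchor <- round(config@tadNearFraction * length(g1ids))
  anchors <- if (nAnchor > 0) sample(g1ids, nAnchor) else character(0)
  anchors <- anchors[order(mids[anchors])]
  tadStarts <- numeric(0); tadEnds <- numeric(0)
  tadPlanted <- numeric(0)
  lastEnd <- 0
  minGap <- 5e3
  for (id in anchors) {
    m <- mids[id]
    d <- floor(runif(1, 0, config@tadNearWindow))
    L <- floor(runif(1, config@tadLenRange[1], config@tadLenRange[2]))
    s <- m - d; e <- s + L - 1                       # border s at distance d
    if (s <= lastEnd + minGap || e > G - minGap) {
      e2 <- m + d; s2 <- e2 - L + 1                  # try the other side
      if (s2 > lastEnd + minGap && e2 <= G - minGap) { s <- s2; e <- e2 }
      else next
    }
    tadStarts <- c(tadStarts, s); tadEnds <- c(tadEnds, e)
    tadPlanted[id] <- d
    lastEnd <- e
  }
  # filler TADs in the remaining gaps
  bounds <- if (!length(tadStarts)) matrix(c(0, G), 1) else
    rbind(c(0, tadStarts[1]),
          if (length(tadStarts) > 1)
            cbind(tadEnds[-length(tadEnds)], tadStarts[-1]),
          c(tadEnds[length(tadEnds)], G))
  fillS <- numeric(0); fillE <- numeric(0)
  for (k in seq_len(nrow(bounds))) {
    pos <- bounds[k, 1]
    while (TRUE) {
      gap <- floor(runif(1, minGap, 2e4))
      L <- floor(runif(1, config@tadLenRange[1], config@tadLenRange[2]))
      if (pos + gap + L >= bounds[k, 2] - minGap) break
      fillS <- c(fillS, pos + gap)
      fillE <- c(fillE, pos + gap + L - 1)
      pos <- pos + gap + L
    }
  }
  o <- order(c(tadStarts, fillS))
  tads <- GRanges(config@chromName,
                  IRanges(as.integer(c(tadStarts, fillS)[o]),
                          as.integer(c(tadEnds, fillE)[o])))

  ## ---- LADs ----
  nAnchorL <- round(config@ladNearFraction * length(g1ids))
  anchorsL <- if (nAnchorL > 0) sample(g1ids, nAnchorL) else character(0)
  anchorsL <- anchorsL[order(mids[anchorsL])]
  protect <- config@ladFarOffset + 5e4
  ladS <- numeric(0); ladE <- numeric(0)
  ladPlanted <- numeric(0)
  minStart <- 1
  for (id in anchorsL) {
    m <- mids[id]
    d <- if (runif(1) < config@ladFarProb) config@ladFarOffset
         else floor(runif(1, 1, config@ladUniformMax))
    L <- floor(runif(1, config@ladLenRange[1], config@ladLenRange[2]))
    e <- m - d; s <- e - L + 1                       # LAD ends d bp left of m
    if (s <= minStart || e <= 0) next
    ladS <- c(ladS, s); ladE <- c(ladE, e)
    ladPlanted[id] <- d
    minStart <- m + protect     # later LADs stay clear of this anchor
  }
  lads <- GRanges(config@chromName,
                  IRanges(as.integer(ladS), as.integer(ladE)))
  lads$source <- "tdnascape_sim"
  lads$type <- "LAD"

  tadD <- nearestBorderDistance(tdnas, tads)
  ladD <- nearestBorderDistance(tdnas, lads)
  truth@domains <- list(
    tadDistance = stats::setNames(tadD$distance, tadD$tdna_id),
    ladDistance = stats::setNames(ladD$distance, ladD$tdna_id),
    tadPlanted = tadPlanted, ladPlanted = ladPlanted)
  list(tads = tads, lads = lads, truth = truth)
}

#' Simulate DHS and conserved-element tracks correlated with group label
#'
#' Per cell line, each locus carries a DHS with probability
#' `dhsFractions[group]` (a peak covering the locus with random flanks);
#' a single conserved-element track likewise uses `consFractions[group]`.
#' Background intervals are placed genome-wide but rejected within `guardBand`
#' of any locus, so the per-group overlap fractions recovered downstream are
#' exactly the planted Bernoulli draws.
#'
#' @param tdnas a [TDNASet-class].
#' @param truth the matching [GroundTruth-class] (labels required).
#' @param config the [SimConfig-class].
#' @return list with `dhs` ([PeakCollection-class], factor `"DHS"` per cell
#'   line), `conserved` (`GRanges`) and updated `truth`.
#' @export
simulateTracks <- function(tdnas, truth, config) {
  set.seed(.stageSeed(config, 303L))
  gr <- loci(tdnas)
  ids <- tdnaIds(tdnas)
  n <- length(ids)
  labels <- truthLabels(truth)[ids]
  cells <- sprintf("cell%02d", seq_len(config@nCellLines))
  chrom <- config@chromName
  guard <- IRanges(pmax(1L, start(gr) - as.integer(config@guardBand)),
                   end(gr) + as.integer(config@guardBand))

  coverPeak <- function(idx) {
    ext1 <- as.integer(floor(runif(length(idx), 50, 200)))
    ext2 <- as.integer(floor(runif(length(idx), 50, 200)))
    GRanges(chrom, IRanges(pmax(1L, start(gr)[idx] - ext1), end(gr)[idx] + ext2))
  }
  background <- function(density, lenRange) {
    nbg <- stats::rpois(1L, density * config@genomeLength / 1e6)
    lens <- as.integer(floor(runif(nbg, lenRange[1], lenRange[2])))
    st <- as.integer(floor(runif(nbg) * (config@genomeLength - lens))) + 1L
    ir <- IRanges(st, width = lens)
    ir <- ir[!IRanges::overlapsAny(ir, guard)]
    GRanges(chrom, ir)
  }

  dhsMat <- matrix(FALSE, n, config@nCellLines, dimnames = list(ids, cells))
  dhsList <- vector("list", config@nCellLines)
  names(dhsList) <- cells
  if (config@nCellLines > 0) {
    for (ci in seq_len(config@nCellLines)) {
      hit <- runif(n) < config@dhsFractions[labels]
      dhsMat[, ci] <- hit
      planted <- coverPeak(which(hit))
      dhsList[[ci]] <- list(DHS = sort(c(planted, background(
        config@dhsBackgroundDensity, c(150, 600)))))
    }
  }

  consHit <- runif(n) < config@consFractions[labels]
  names(consHit) <- ids
  conserved <- sort(c(coverPeak(which(consHit)),
                      background(config@consBackgroundDensity, c(50, 400))))

  truth@tracks <- list(dhs = dhsMat, conserved = consHit)
  list(dhs = PeakCollection(dhsList), conserved = conserved, truth = truth)
}

#' Run the full synthetic-data generator
#'
#' Chains [simulateTdnas()], [simulatePeaks()], [simulateDomains()] and
#' [simulateTracks()] under the configured seed.
#'
#' @param config a [SimConfig-class].
#' @param pwm the [PWMotif] planted into sequences.
#' @return list with `config`, `pwm`, `tdnas`, `truth`, `peaks`, `tads`,
#'   `lads`, `dhs`, `conserved`.
#' @examples
#' sim <- simulateAll(simConfig(seed = 3, nTdnas = 40, nCellLines = 2,
#'                              nTfsPerCell = 10, genomeLength = 2e7,
#'                              nCohesin = 3, nCohesinAllCells = 1))
#' groupSizes(classifyGroups(countTfs(sim$tdnas, sim$peaks)))
#' @export
simulateAll <- function(config, pwm = ctcfToyPwm()) {
  td <- simulateTdnas(config, pwm)
  pk <- simulatePeaks(td$tdnas, td$truth, config)
  dm <- simulateDomains(td$tdnas, pk$truth, config)
  tr <- simulateTracks(td$tdnas, dm$truth, config)
  list(config = config, pwm = pwm, tdnas = td$tdnas, truth = tr$truth,
       peaks = pk$peaks, tads = dm$tads, lads = dm$lads,
       dhs = tr$dhs, conserved = tr$conserved)
}

#' Write a simulation to disk as standard-format files
#'
#' Emits BED6 for loci, ChIP peaks (one file per cell line and factor, with a
#' tab-separated manifest), DHS peaks, TADs and conserved elements; GFF3 for
#' LADs; FASTA for locus sequences; TSVs for the structural segmentations and
#' the ground truth; and the YAML configuration. Output is deterministic given
#' the simulation object.
#'
#' @param sim result of [simulateAll()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gr <- loci(sim$tdnas)
  gr$name <- gr$tdna_id
  writeBed(gr, file.path(dir, "tdnas.bed"))
  writeFasta(tdnaSequences(sim$tdnas), file.path(dir, "tdnas.fasta"))

  st <- tdnaStructures(sim$tdnas)
  segDf <- do.call(rbind, lapply(names(st), function(id)
    data.frame(tdna_id = id, region = names(st[[id]]),
               start = IRanges::start(st[[id]]), end = IRanges::end(st[[id]]))))
  utils::write.table(segDf, file.path(dir, "structures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pkdir <- file.path(dir, "peaks")
  dir.create(pkdir, showWarnings = FALSE)
  manifest <- NULL
  for (cell in cellLines(sim$peaks)) {
    for (tf in tfNames(sim$peaks, cell)) {
      rel <- file.path("peaks", paste0(cell, "_", tf, ".bed"))
      writeBed(peaksOf(sim$peaks, cell, tf), file.path(dir, rel))
      manifest <- rbind(manifest, data.frame(cell_line = cell, factor = tf,
                                             path = rel))
    }
  }
  utils::write.table(manifest, file.path(dir, "peak_manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  writeBed(sim$tads, file.path(dir, "tads.bed"), dialect = "bed3")
  writeGff(sim$lads, file.path(dir, "lads.gff3"))
  writeBed(sim$conserved, file.path(dir, "conserved.bed"), dialect = "bed3")
  dhsdir <- file.path(dir, "dhs")
  dir.create(dhsdir, showWarnings = FALSE)
  dmanifest <- NULL
  for (cell in cellLines(sim$dhs)) {
    rel <- file.path("dhs", paste0(cell, "_DHS.bed"))
    writeBed(peaksOf(sim$dhs, cell, "DHS"), file.path(dir, rel),
             dialect = "bed3")
    dmanifest <- rbind(dmanifest, data.frame(cell_line = cell, path = rel))
  }
  if (!is.null(dmanifest))
    utils::write.table(dmanifest, file.path(dir, "dhs_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  tr <- sim$truth
  gt <- data.frame(tdna_id = tdnaIds(sim$tdnas),
                   group = truthLabels(tr)[tdnaIds(sim$tdnas)])
  dom <- truthDomains(tr)
  if (length(dom)) {
    gt$tad_distance <- dom$tadDistance[gt$tdna_id]
    gt$lad_distance <- dom$ladDistance[gt$tdna_id]
  }
  tk <- truthTracks(tr)
  if (length(tk)) gt$conserved <- tk$conserved[gt$tdna_id]
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(truthMotifs(tr)))
    utils::write.table(truthMotifs(tr), file.path(dir, "planted_motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writePwm(sim$pwm, file.path(dir, "pwm.txt"))
  writeSimConfig(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Build a PeakCollection from a peak manifest
#'
#' The manifest is a tab-separated file with columns `cell_line`, `factor`,
#' `path` (BED paths relative to the manifest's directory), the format written
#' by [writeSimulation()].
#'
#' @param path manifest file path.
#' @return a [PeakCollection-class].
#' @export
readPeakManifest <- function(path) {
  mf <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cell_line", "factor", "path")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  out <- list()
  for (k in seq_len(nrow(mf))) {
    out[[mf$cell_line[k]]][[mf$factor[k]]] <-
      readBed(file.path(base, mf$path[k]))
  }
  PeakCollection(out)
}
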