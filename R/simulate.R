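## Synthetic-data generator: every pipeline input with planted, known
## structure. Each stage reseeds from config@seed plus a fixed stage offset so
## stages are individually deterministic; a fixed seed gives byte-identical
## emitted files.

.stageSeed <- function(config, offset) {
  as.integer((as.numeric(config@seed) + offset) %% (.Machine$integer.max - 1))
}

.randSeq <- function(n) {
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)], collapse = "")
}

#' Canonical tRNA structural segmentation
#'
#' Fixed template spans (acceptor 5' stem, D-loop, anticodon loop, variable
#' loop, T-loop, acceptor 3' stem) in locus-relative, gene-orientation,
#' 1-based coordinates, scaled proportionally from the 72-bp canonical layout
#' to the requested locus length.
#'
#' @param len locus length in bp (>= 30).
#' @return an `IRanges` with names `acceptor5`, `dloop`, `anticodon`,
#'   `variable`, `tloop`, `acceptor3`.
#' @export
canonicalSegmentation <- function(len) {
  stopifnot(len >= 30)
  # canonical spans on a 72-nt tRNA gene
  template <- rbind(acceptor5 = c(1, 7), dloop = c(14, 22),
                    anticodon = c(31, 38), variable = c(44, 47),
                    tloop = c(53, 60), acceptor3 = c(66, 72))
  s <- pmax(1L, as.integer(round(template[, 1] * len / 72)))
  e <- pmin(as.integer(len), as.integer(round(template[, 2] * len / 72)))
  IRanges(s, e, names = rownames(template))
}

#' Simulate tDNA loci with sequences, structures and planted motifs
#'
#' Places `nTdnas` non-overlapping loci (minimum gap `minLocusGap`) on one
#' synthetic chromosome, assigns each a uniform random strand, a random
#' gene-strand sequence and the canonical structural segmentation, draws
#' planted group labels with the configured fractions, and writes the PWM
#' consensus into a `motifPlantFraction` subset of sequences at a recorded
#' offset and strand (reverse-complemented for "n"-strand plants).
#'
#' @param config a [SimConfig-class].
#' @param pwm the [PWMotif] whose consensus is planted (default the shipped
#'   synthetic CTCF-like PWM).
#' @return list with elements `tdnas` ([TDNASet-class]) and `truth`
#'   ([GroundTruth-class] with `labels` and `motifs` filled).
#' @export
simulateTdnas <- function(config, pwm = ctcfToyPwm()) {
  set.seed(.stageSeed(config, 0L))
  n <- config@nTdnas
  len <- config@tdnaLength
  margin <- min(3e6, config@genomeLength * 0.03)
  slot_ <- len + config@minLocusGap
  free <- config@genomeLength - 2 * margin - n * slot_
  if (free <= 0)
    stop("cannot place ", n, " loci without overlap on a ",
         config@genomeLength, "-bp chromosome; increase genomeLength")
  u <- sort(runif(n, 0, free))
  starts <- as.integer(round(margin + u + (seq_len(n) - 1L) * slot_)) + 1L
  ids <- sprintf("tDNA-%04d", seq_len(n))
  gr <- GRanges(config@chromName, IRanges(starts, width = len),
                strand = sample(c("+", "-"), n, replace = TRUE),
                tdna_id = ids)

  # planted group labels, exact counts per configured fractions
  counts <- floor(config@groupFractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(config@groupFractions * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  labels <- sample(rep.int(1:3, counts))
  names(labels) <- ids

  seqs <- vapply(seq_len(n), function(i) .randSeq(len), character(1))

  w <- pwmWidth(pwm)
  cons <- consensusSequence(pwm)
  nPlant <- round(config@motifPlantFraction * n)
  motifs <- data.frame(tdna_id = character(), start = integer(),
                       strand = character(), width = integer(),
                       stringsAsFactors = FALSE)
  if (nPlant > 0) {
    if (len < w) stop("tdnaLength shorter than the PWM width; nothing to plant")
    planted <- sort(sample.int(n, nPlant))
    offs <- sample.int(len - w + 1L, nPlant, replace = TRUE)
    strs <- sample(c("p", "n"), nPlant, replace = TRUE)
    ins <- ifelse(strs == "p", cons,
                  as.character(reverseComplement(DNAStringSet(cons))))
    for (k in seq_len(nPlant)) {
      i <- planted[k]
      substr(seqs[i], offs[k], offs[k] + w - 1L) <- ins[k]
    }
    motifs <- data.frame(tdna_id = ids[planted], start = offs,
                         strand = strs, width = w, stringsAsFactors = FALSE)
  }
  sset <- DNAStringSet(seqs)
  names(sset) <- ids
  structures <- rep(list(canonicalSegmentation(len)), n)
  names(structures) <- ids
  tdnas <- TDNASet(gr, sequences = sset, structures = structures)
  truth <- new("GroundTruth", labels = labels, motifs = motifs,
               peaks = list(), domains = list(), tracks = list())
  list(tdnas = tdnas, truth = truth)
}

# one planted peak per (locus, factor): random length within range, positioned
# uniformly among all placements overlapping the locus by >= 1 bp
.plantPeaks <- function(ls, le, lens) {
  lo <- ls - lens + 1L
  st <- lo + floor(runif(length(lens)) * (le - lo + 1L))
  IRanges(as.integer(st), width = lens)
}

.drawLens <- function(n, range) {
  as.integer(range[1] + floor(runif(n) * (range[2] - range[1] + 1)))
}

#' Simulate multi-cell-line TF ChIP peaks realizing the planted groups
#'
#' For each cell line, Group-1 loci receive peaks from a
#' Binomial(`nTfsPerCell`, theta) sample of TFs (theta is the locus's shared
#' binding propensity); Group-2 loci receive Group-1-like peaks in their bound
#' cell lines (at least one bound, at least one unbound) and none elsewhere;
#' Group-3 loci receive none, enforced by rejecting background peaks within a
#' `guardBand` of them. Poisson background peaks are placed genome-wide per
#' TF. CTCF, RAD21 and SMC3 are reserved names used only for planting: a
#' `ctcfConfirmFraction` subset of the motif-planted (non-Group-3) loci gets an
#' overlapping CTCF peak, and `nCohesin` loci get CTCF+RAD21+SMC3 triple
#' colocalization (`nCohesinAllCells` of them in every cell line, the rest in
#' a random proper non-empty subset).
#'
#' @param tdnas a [TDNASet-class] from [simulateTdnas()].
#' @param truth the matching [GroundTruth-class].
#' @param config the [SimConfig-class].
#' @return list with elements `peaks` ([PeakCollection-class]) and updated
#'   `truth`.
#' @export
simulatePeaks <- function(tdnas, truth, config) {
  set.seed(.stageSeed(config, 101L))
  n <- length(tdnas)
  gr <- loci(tdnas)
  ids <- tdnaIds(tdnas)
  labels <- truthLabels(truth)[ids]
  cells <- sprintf("cell%02d", seq_len(config@nCellLines))
  tfs <- sprintf("TF%03d", seq_len(config@nTfsPerCell))
  chrom <- config@chromName

  theta <- numeric(n)
  g1 <- labels == 1L; g2 <- labels == 2L; g3 <- labels == 3L
  theta[g1] <- runif(sum(g1), max(0, config@group1TfRate - config@group1TfSpread),
                     min(1, config@group1TfRate + config@group1TfSpread))
  theta[g2] <- runif(sum(g2), max(0, config@group2TfRate - config@group2TfSpread),
                     min(1, config@group2TfRate + config@group2TfSpread))
  names(theta) <- ids

  # expected per-cell-line mean count; warn when Group-1 loci are not expected
  # to clear it (labels may then not be recoverable)
  f <- config@groupFractions
  mu <- config@nTfsPerCell *
    (f[1] * config@group1TfRate +
       f[2] * config@group2CellSparsity * config@group2TfRate)
  if (config@nTfsPerCell * (config@group1TfRate - config@group1TfSpread) <= mu)
    warning("group1TfRate is low relative to the expected cell-line average (",
            round(mu, 1), "); planted labels may not be recoverable")

  a <- config@group2CellSparsity * config@group2SparsityShape
  b <- config@group2SparsityShape - a
  q <- rep(NA_real_, n)
  q[g2] <- pmin(0.98, pmax(0.02, stats::rbeta(sum(g2), a, b)))
  names(q) <- ids

  nc <- config@nCellLines
  bound <- matrix(FALSE, n, nc, dimnames = list(ids, cells))
  bound[g1, ] <- TRUE
  for (i in which(g2)) {
    repeat {
      v <- stats::runif(nc) < q[i]
      if (nc == 1L || (any(v) && !all(v))) break
    }
    if (nc == 1L) v <- TRUE   # degenerate single-cell config: bound
    bound[i, ] <- v
  }

  guard <- GRanges(chrom, IRanges(pmax(1L, start(gr)[g3] - as.integer(config@guardBand)),
                                  end(gr)[g3] + as.integer(config@guardBand)))

  motifLoci <- unique(truthMotifs(truth)$tdna_id)
  eligibleConfirm <- setdiff(motifLoci, ids[g3])
  nConfirm <- min(length(eligibleConfirm),
                  round(config@ctcfConfirmFraction * length(motifLoci)))
  confirmLoci <- if (nConfirm > 0) sort(sample(eligibleConfirm, nConfirm))
                 else character(0)

  cohesinPool <- setdiff(ids[!g3], setdiff(motifLoci, confirmLoci))
  nCoh <- min(config@nCohesin, length(cohesinPool))
  cohesinLoci <- if (nCoh > 0) sort(sample(cohesinPool, nCoh)) else character(0)
  nAll <- min(config@nCohesinAllCells, nCoh)
  cohesinAll <- if (nAll > 0) cohesinLoci[seq_len(nAll)] else character(0)
  cohesinCells <- lapply(cohesinLoci, function(id) {
    if (id %in% cohesinAll || nc == 1L) cells
    else sort(sample(cells, sample.int(max(1L, nc - 1L), 1L)))
  })
  names(cohesinCells) <- cohesinLoci

  lambda <- config@backgroundPeakDensity * config@genomeLength / 1e6
  collection <- vector("list", nc)
  names(collection) <- cells
  for (ci in seq_len(nc)) {
    cell <- cells[ci]
    # planted factor draws for every bound locus in this cell
    bl <- which(bound[, ci])
    perLocus <- lapply(bl, function(i) {
      k <- stats::rbinom(1L, config@nTfsPerCell, theta[i])
      if (k > 0) sample.int(config@nTfsPerCell, k) else integer(0)
    })
    locusIdx <- rep(bl, lengths(perLocus))
    tfIdx <- unlist(perLocus, use.names = FALSE)
    plantedIR <- if (length(locusIdx))
      .plantPeaks(start(gr)[locusIdx], end(gr)[locusIdx],
                  .drawLens(length(locusIdx), config@peakLenRange))
    else IRanges()

    # genome-wide Poisson background per TF, rejected inside Group-3 guards
    nbg <- stats::rpois(config@nTfsPerCell, lambda)
    bgTf <- rep.int(seq_len(config@nTfsPerCell), nbg)
    bgLens <- .drawLens(length(bgTf), config@peakLenRange)
    bgStart <- as.integer(floor(runif(length(bgTf)) *
                                  (config@genomeLength - bgLens))) + 1L
    bgIR <- IRanges(bgStart, width = bgLens)
    if (length(guard) && length(bgIR)) {
      drop_ <- IRanges::overlapsAny(bgIR, IRanges::ranges(guard))
      bgIR <- bgIR[!drop_]; bgTf <- bgTf[!drop_]
    }

    allTf <- c(tfIdx, bgTf)
    allIR <- c(plantedIR, bgIR)
    fl <- lapply(seq_len(config@nTfsPerCell), function(fi) {
      GRanges(chrom, allIR[allTf == fi])
    })
    names(fl) <- tfs
    collection[[ci]] <- fl
  }

  # reserved factors: assemble per cell from the planting plans
  confirmCellPlan <- lapply(confirmLoci, function(id)
    sort(sample(cells, sample.int(nc, 1L))))
  names(confirmCellPlan) <- confirmLoci
  for (ci in seq_len(nc)) {
    cell <- cells[ci]
    ctcfIds <- c(confirmLoci[vapply(confirmLoci, function(id)
                   cell %in% confirmCellPlan[[id]], logical(1))],
                 cohesinLoci[vapply(cohesinLoci, function(id)
                   cell %in% cohesinCells[[id]], logical(1))])
    ctcfIds <- unique(ctcfIds)
    cohIds <- cohesinLoci[vapply(cohesinLoci, function(id)
      cell %in% cohesinCells[[id]], logical(1))]
    mk <- function(idset) {
      if (!length(idset)) return(GRanges())
      idx <- match(idset, ids)
      GRanges(chrom, .plantPeaks(start(gr)[idx], end(gr)[idx],
                                 .drawLens(length(idx), config@peakLenRange)))
    }
    collection[[ci]]$CTCF <- mk(ctcfIds)
    collection[[ci]]$RAD21 <- mk(cohIds)
    collection[[ci]]$SMC3 <- mk(cohIds)
  }

  cohesinDf <- if (length(cohesinLoci))
    data.frame(tdna_id = rep(cohesinLoci, lengths(cohesinCells)),
               cell_line = unlist(cohesinCells, use.names = FALSE),
               stringsAsFactors = FALSE)
  else data.frame(tdna_id = character(), cell_line = character(),
                  stringsAsFactors = FALSE)

  truth@peaks <- list(theta = theta, q = q, boundCells = bound,
                      cohesin = cohesinDf, cohesinAllCells = cohesinAll,
                      ctcfConfirmed = confirmLoci,
                      confirmCells = confirmCellPlan)
  list(peaks = PeakCollection(collection), truth = truth)
}
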