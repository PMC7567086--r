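## Combined report generator: runs the full pipeline on a simulation (or a
## pre-built set of inputs) and writes the standard TSV bundle plus a
## machine-readable run manifest. Percentages are rendered to one decimal
## place; raw counts are always emitted alongside.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Generates (or accepts) a synthetic dataset, then runs the TF census and
#' classification, per-group TF frequency tables, the positional landscape,
#' the PWM scan with ChIP confirmation and structural-region assignment,
#' cohesin colocalization, and the TAD/LAD/DHS/conservation context, writing
#' one TSV per result plus `manifest.json` (configuration echo, output
#' checksums, package version). Outputs are deterministic given the
#' configuration seed. On error, partially written outputs are removed.
#'
#' @param config a [SimConfig-class] (or a path to a YAML config file).
#' @param outDir output directory.
#' @param pwm the [PWMotif] used for planting and scanning.
#' @param landscapeCell cell line profiled in the landscape TSV (default the
#'   first).
#' @param writeInputs also write the simulated inputs under `outDir/sim/`.
#' @return (invisibly) a list with the in-memory results: `sim`, `counts`,
#'   `countsTotal`, `groups`, `landscape`, `hits`, `cohesin`, `summary`
#'   (data.frame of containment/overlap fractions), `paths`.
#' @export
runReport <- function(config, outDir, pwm = ctcfToyPwm(),
                      landscapeCell = NULL, writeInputs = FALSE) {
  if (is.character(config)) config <- readSimConfig(config)
  started <- dir.exists(outDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(written)
      if (!started) unlink(outDir, recursive = TRUE)
    }
  })
  message("tdnascape: seed ", config@seed, ", ", config@nTdnas, " loci, ",
          config@nCellLines, " cell lines x ", config@nTfsPerCell,
          " TFs; peak length cap ", config@peakLenRange[2],
          " bp; motif threshold ", pwm@threshold)

  sim <- simulateAll(config, pwm)
  if (writeInputs) writeSimulation(sim, file.path(outDir, "sim"))

  cells <- cellLines(sim$peaks)
  counts <- countTfs(sim$tdnas, sim$peaks)
  countsTotal <- countTfs(sim$tdnas, sim$peaks, mode = "total")
  groups <- classifyGroups(counts)

  tab1 <- data.frame(tdna_id = rownames(counts))
  for (cell in cells) {
    tab1[[paste0("unique_", cell)]] <- counts[, cell]
    tab1[[paste0("total_", cell)]] <- countsTotal[, cell]
  }
  written <- c(written, .writeTsv(tab1, file.path(outDir, "tf_counts.tsv")))

  gdf <- data.frame(tdna_id = names(groupOf(groups)), group = groupOf(groups))
  written <- c(written, .writeTsv(gdf, file.path(outDir, "groups.tsv")))

  freq <- do.call(rbind, lapply(cells, function(cell) {
    f <- tfFrequencyByGroup(sim$tdnas, sim$peaks, groups, cell, group = 1L)
    f$percent <- round(f$percent, 1)
    cbind(cell_line = cell, f)
  }))
  written <- c(written, .writeTsv(freq, file.path(outDir,
                                                  "tf_frequency_group1.tsv")))

  if (is.null(landscapeCell)) landscapeCell <- cells[1]
  land <- distanceLandscape(sim$tdnas, sim$peaks, landscapeCell)
  written <- c(written, .writeTsv(land, file.path(outDir, paste0(
    "landscape_", landscapeCell, ".tsv"))))

  hits <- scanPwm(pwm, sim$tdnas)
  hits <- confirmHits(hits, sim$peaks, tdnas = sim$tdnas)$hits
  hits <- assignStructuralRegion(hits, sim$tdnas)
  tab3 <- hits[order(-hits$score), c("tdna_id", "matched", "strand", "score",
                                     "chip_confirmed", "structural_region")]
  names(tab3)[2] <- "motif_5to3"
  written <- c(written, .writeTsv(tab3, file.path(outDir, "motif_hits.tsv")))

  coh <- cohesinColocalization(sim$tdnas, sim$peaks)
  written <- c(written, .writeTsv(coh$byCell,
                                  file.path(outDir, "cohesin_colocalization.tsv")))

  prof <- borderProfile(sim$tdnas, sim$tads, groups, window = 5e5, bin = 1e4)
  written <- c(written, .writeTsv(prof, file.path(outDir,
                                                  "border_profile_tad.tsv")))
  profL <- borderProfile(sim$tdnas, sim$lads, groups, window = 1.5e5, bin = 5e3)
  written <- c(written, .writeTsv(profL, file.path(outDir,
                                                   "border_profile_lad.tsv")))

  rows <- list()
  for (g in 1:3) {
    members <- groupMembers(groups, g)
    if (!length(members)) next
    sub <- sim$tdnas[tdnaIds(sim$tdnas) %in% members]
    cf <- containmentFraction(sub, sim$tads)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "tad_containment", group = g, cell_line = NA,
      numerator = cf$inside, denominator = cf$total,
      percent = round(cf$percent, 1))
    ov <- trackOverlapFraction(sub, sim$conserved)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "conserved_overlap", group = g, cell_line = NA,
      numerator = ov$overlapping, denominator = ov$total,
      percent = round(ov$percent, 1))
    for (cell in cellLines(sim$dhs)) {
      dv <- trackOverlapFraction(sub, peaksOf(sim$dhs, cell, "DHS"))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "dhs_overlap", group = g, cell_line = cell,
        numerator = dv$overlapping, denominator = dv$total,
        percent = round(dv$percent, 1))
    }
  }
  summary_ <- do.call(rbind, rows)
  written <- c(written, .writeTsv(summary_, file.path(outDir,
                                                      "domain_summary.tsv")))

  cfgPath <- file.path(outDir, "config.yaml")
  writeSimConfig(config, cfgPath)
  written <- c(written, cfgPath)
  manifest <- list(
    tool = "tdnascape",
    version = as.character(utils::packageVersion("tdnascape")),
    seed = config@seed,
    pwm = pwm@name,
    thresholds = list(overlap_min_bp = 1, peak_max_len = config@peakLenRange[2],
                      motif_threshold = pwm@threshold,
                      cell_specific_hi = 20, cell_specific_lo = 5),
    outputs = {
      w <- sort(written)
      rel <- ifelse(startsWith(w, paste0(outDir, "/")),
                    substring(w, nchar(outDir) + 2L), basename(w))
      stats::setNames(as.list(unname(tools::md5sum(w))), rel)
    })
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(list(sim = sim, counts = counts, countsTotal = countsTotal,
                 groups = groups, landscape = land, hits = hits,
                 cohesin = coh, summary = summary_,
                 paths = c(written, file.path(outDir, "manifest.json"))))
}
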