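# End-to-end experiment drivers: the migration-rate D-statistic grid, the
# Y-fixation selection grid, and the consolidated genome-scan report.

#' Migration-rate grid of simulated D-statistics
#'
#' For each migration proportion on the grid, simulates replicate
#' multi-locus datasets under [guenonModel()] with the mitis -> denti pulse
#' set to that rate (the two ancestral pulses always included), computes
#' the frequency-weighted D-statistic
#' (P1 = wolfi, P2 = denti, P3 = mitis, outgroup = macaque) and its
#' 20-block jackknife Z-score per replicate, and reports the smallest rate
#' above which every replicate is significantly positive (Z > 3).
#'
#' @param rates Migration proportions (default 0 to 1 percent in 0.05
#'   percent steps).
#' @param nReplicates Replicates per rate.
#' @param lociCount,lociLength Independent loci per replicate and their
#'   length. The default locus count is sized so that the jackknife
#'   standard error of D matches the precision of the study design this
#'   grid stands in for (100 Mb of recombining sequence, within which
#'   ancestral recombination decorrelates genealogies far below the 1 Mb
#'   locus scale); see the methods vignette.
#' @param samplesPerTaxon Diploid individuals sampled per taxon.
#' @param nBlocks Jackknife blocks (loci grouped contiguously).
#' @param seed Master seed (expanded per rate x replicate with
#'   [deriveSeed()]).
#' @param verbose Print a progress line per rate.
#' @return A list with `table` (rate, replicate, D, Z, significant),
#'   `perRate` (rate, nSignificant), `thresholdRate` (the smallest rate at
#'   which every replicate is significant; `NA` if none), and
#'   `consistentRate` (the stricter smallest rate such that this and every
#'   larger rate has all replicates significant).
#' @export
runFig6aExperiment <- function(rates = seq(0, 0.01, by = 0.0005),
                               nReplicates = 10, lociCount = 155000,
                               lociLength = 10000, samplesPerTaxon = 1,
                               nBlocks = 20, seed = 1, verbose = FALSE) {
  samples <- c(wolfi = samplesPerTaxon, denti = samplesPerTaxon,
               mitis = samplesPerTaxon, macaque = samplesPerTaxon)
  rows <- list()
  for (ri in seq_along(rates)) {
    model <- guenonModel(phi3 = rates[ri])
    for (rep in seq_len(nReplicates)) {
      counts <- simulateAbbaCounts(model, lociCount, lociLength, samples,
                                   "wolfi", "denti", "mitis", "macaque",
                                   nBlocks = nBlocks,
                                   seed = deriveSeed(seed, ri, rep))
      jk <- blockJackknifeZ(counts)
      rows[[length(rows) + 1]] <- data.frame(
        rate = rates[ri], replicate = rep, d = jk$d, z = jk$z,
        significant = is.finite(jk$z) && jk$z > 3)
    }
    if (verbose)
      message(sprintf("rate %.4f: %d/%d significant", rates[ri],
                      sum(vapply(tail(rows, nReplicates), `[[`, logical(1),
                                 "significant")), nReplicates))
  }
  table <- do.call(rbind, rows)
  perRate <- stats::aggregate(significant ~ rate, table, sum)
  names(perRate)[2] <- "nSignificant"
  allSig <- perRate$nSignificant == nReplicates
  thresholdRate <- if (any(allSig)) min(perRate$rate[allSig]) else NA_real_
  # stricter variant: significant at this and every larger rate
  consistent <- rev(cumprod(rev(allSig))) == 1
  consistentRate <- if (any(consistent)) min(perRate$rate[consistent]) else
    NA_real_
  list(table = table, perRate = perRate, thresholdRate = thresholdRate,
       consistentRate = consistentRate)
}

# contiguous grouping of whole loci into jackknife blocks
.lociBlocks <- function(gm, nBlocks) {
  loci <- unique(gm@chrom)
  grp <- setNames(1L + ((seq_along(loci) - 1L) * nBlocks) %/% length(loci),
                  loci)
  sprintf("block%02d", grp[gm@chrom])
}

#' Y-fixation rates over a selection / initial-frequency grid
#'
#' Runs [fixationRate()] for every combination of selection coefficient and
#' initial Y frequency and tabulates the fixed / lost / segregating
#' fractions next to the Kimura diffusion prediction.
#'
#' @param sGrid Selection coefficients.
#' @param p0Grid Initial Y frequencies (the default six-point 0.1-1 percent
#'   panel).
#' @param nYCopies Y copies (census individuals / 2).
#' @param maxGens Generations per replicate.
#' @param nReps Replicates per cell.
#' @param seed Master seed.
#' @return data.frame with one row per cell: `s`, `p0`, `fixed`, `lost`,
#'   `segregating`, `ciLower`, `ciUpper`, `kimura`.
#' @export
runFig6bExperiment <- function(sGrid = c(0, 0.001, 0.01),
                               p0Grid = c(0.001, 0.002, 0.004, 0.006,
                                          0.008, 0.01),
                               nYCopies = 100000, maxGens = 100000,
                               nReps = 100, seed = 1) {
  grid <- expand.grid(s = sGrid, p0 = p0Grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fr <- fixationRate(nYCopies, grid$s[i], grid$p0[i], maxGens = maxGens,
                       nReps = nReps, seed = deriveSeed(seed, 60, i))
    data.frame(s = grid$s[i], p0 = grid$p0[i], fixed = fr$fixed,
               lost = fr$lost, segregating = fr$segregating,
               ciLower = fr$ci["lower"], ciUpper = fr$ci["upper"],
               kimura = kimuraFixationProbability(nYCopies, grid$s[i],
                                                  grid$p0[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consolidated genome scans over a synthetic or user dataset
#'
#' Orchestrates the window statistics on a genotype dataset (D with
#' jackknife Z, windowed f_d and dXY, sliding-window topology
#' classification) and, when coverage tracks or CDS alignments are
#' supplied, the PAR / CNV coverage scans and the coding screen. Outputs
#' are written as TSV/BED under `outDir` together with a markdown summary;
#' every stage is logged with its row counts.
#'
#' @param gm A [GenotypeMatrix-class] (e.g. from [readGenotypeVcf()] or
#'   [generateStudyGenotypes()]).
#' @param p1,p2,p3,outgroup Populations for D / f_d.
#' @param dxyPops Character vector of two populations for dXY.
#' @param taxa Optional data.frame (sample, species, group) enabling the
#'   topology scan; see [scanGenomeTopology()].
#' @param focal,donorSpecies,speciesSister Topology-scan species
#'   (defaulting to the guenon design).
#' @param coverage Optional list from [generateCoverageTracks()] (or with
#'   the same shape) enabling the PAR and CNV scans.
#' @param cds Optional list with `files`, `cladeA`, `cladeB` enabling the
#'   coding screen.
#' @param windowBpDxy,windowBpTopo Window sizes.
#' @param outDir Output directory.
#' @param completeCoverage Passed to [dxyWindows()].
#' @return Invisibly, a named list of stage results (also written to
#'   `outDir`).
#' @export
runGenomeScans <- function(gm, p1 = "wolfi", p2 = "denti", p3 = "mitis",
                           outgroup = "macaque",
                           dxyPops = c("denti", "mitis"), taxa = NULL,
                           focal = "denti", donorSpecies = "mitis",
                           speciesSister = "wolfi", coverage = NULL,
                           cds = NULL, windowBpDxy = 50000,
                           windowBpTopo = 10000, outDir = tempfile("scans"),
                           completeCoverage = FALSE) {
  .check(is(gm, "GenotypeMatrix"), "gm must be a GenotypeMatrix")
  .check(nSites(gm) > 0, "genotype matrix is empty")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log <<- c(log, sprintf("- %s: %s rows", name,
                           if (is.data.frame(res)) nrow(res) else
                             length(res)))
    res
  }
  report <- list()
  counts <- stage("dstat", abbaBabaCounts(gm, p1, p2, p3, outgroup))
  report$dstat <- c(blockJackknifeZ(counts),
                    list(nSitesUsed = counts@nSitesUsed))
  report$fd <- stage("fd", fdWindows(gm, p1, p2, p3, outgroup,
                                     windowBp = windowBpTopo))
  write.table(report$fd, file.path(outDir, "fd_windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$dxy <- stage("dxy", dxyWindows(gm, dxyPops[1], dxyPops[2],
                                        windowBp = windowBpDxy,
                                        completeCoverage = completeCoverage,
                                        minSites = 1))
  write.table(report$dxy, file.path(outDir, "dxy_windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(taxa)) {
    report$topology <- stage("topology", scanGenomeTopology(
      gm, taxa, focal, donorSpecies, outgroup, speciesSister,
      windowBp = windowBpTopo)$windows)
    write.table(report$topology, file.path(outDir, "topology_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(coverage)) {
    maleN <- normalizeCoverage(rbind(coverage$maleX, coverage$autoMale),
                               "autosomal_mean")
    femaleN <- normalizeCoverage(rbind(coverage$femaleX, coverage$autoMale),
                                 "autosomal_mean")
    report$par <- stage("par", detectPar(
      maleN[maleN$chrom == coverage$maleX$chrom[1], ],
      femaleN[femaleN$chrom == coverage$maleX$chrom[1], ])$par)
    if (nrow(report$par))
      writeBed(report$par, file.path(outDir, "par.bed"))
    report$cnv <- stage("cnv", cnvRatioScan(
      normalizeCoverage(coverage$cnvTarget, "chromosome_mean"),
      normalizeCoverage(coverage$cnvReference, "chromosome_mean")))
    if (nrow(report$cnv))
      writeBed(report$cnv, file.path(outDir, "cnv.bed"))
  }
  if (!is.null(cds))
    report$coding <- stage("coding", codingScreen(cds$files, cds$cladeA,
                                                  cds$cladeB))
  md <- c("# Genome scan summary", "",
          sprintf("D = %.4f, Z = %.2f (%d sites)", report$dstat$d,
                  report$dstat$z, report$dstat$nSitesUsed), "", log)
  writeLines(md, file.path(outDir, "summary.md"))
  invisible(report)
}
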