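# Synthetic-data generators: every input the pipeline consumes can be
# produced deterministically from a seed, together with a machine-readable
# truth file sufficient to score the downstream modules.

#' Generate a study-design genotype fixture
#'
#' Simulates genotypes for the nine-taxon guenon design under
#' [guenonModel()] (optionally its Y-linked derivation), writes a VCF with
#' explicit invariant-site records, a two-column population map, and a JSON
#' truth file recording the seed and every pulse proportion.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed; the same seed reproduces the files
#'   byte-identically.
#' @param phi3 mitis -> denti pulse proportion (autosomal scale; doubled
#'   automatically in `y_linked` mode by [deriveYModel()]).
#' @param mode `"autosomal"` or `"y_linked"`.
#' @param lociCount,lociLength Number and length (bp) of independent loci.
#' @param samplesPerTaxon Individuals sampled per taxon.
#' @param taxa Populations to sample.
#' @return Invisibly, a list with paths (`vcf`, `popmap`, `truth`) and the
#'   in-memory [GenotypeMatrix-class].
#' @export
generateStudyGenotypes <- function(outDir, seed, phi3 = 0.002,
                                   mode = c("autosomal", "y_linked"),
                                   lociCount = 20, lociLength = 1000,
                                   samplesPerTaxon = 1,
                                   taxa = c("denti", "wolfi", "pogonias",
                                            "mona", "neglectus", "cephus",
                                            "nictitans", "mitis",
                                            "macaque")) {
  mode <- match.arg(mode)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  model <- guenonModel(phi3 = phi3)
  if (mode == "y_linked") model <- deriveYModel(model)
  samples <- setNames(rep(samplesPerTaxon, length(taxa)), taxa)
  gm <- simulateGenotypeMatrix(model, lociCount, lociLength, samples,
                               seed = seed)
  gmFull <- .withInvariantSites(gm)
  vcf <- file.path(outDir, "genotypes.vcf")
  writeGenotypeVcf(gmFull, vcf)
  popmap <- file.path(outDir, "popmap.tsv")
  write.table(data.frame(sample = names(gm@popMap),
                         population = unname(gm@popMap)),
              popmap, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  truth <- file.path(outDir, "truth.json")
  pu <- model@pulses
  jsonlite::write_json(
    list(seed = seed, mode = mode, phi3 = phi3,
         effectivePulses = pu, lociCount = lociCount,
         lociLength = lociLength, samplesPerTaxon = samplesPerTaxon),
    truth, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(vcf = vcf, popmap = popmap, truth = truth, matrix = gm))
}

# expand a simulated matrix to carry one record per position (invariant
# records with dosage 0; pixy convention so dXY denominators are explicit)
.withInvariantSites <- function(gm) {
  chroms <- names(gm@chromLengths)
  allChrom <- rep(chroms, times = gm@chromLengths)
  allPos <- unlist(lapply(gm@chromLengths, seq_len), use.names = FALSE)
  geno <- matrix(0L, nrow = length(allPos), ncol = ncol(gm@geno),
                 dimnames = list(NULL, colnames(gm@geno)))
  key <- paste(gm@chrom, gm@pos)
  hit <- match(key, paste(allChrom, allPos))
  geno[hit, ] <- gm@geno
  new("GenotypeMatrix", geno = geno, chrom = allChrom,
      pos = as.integer(allPos), ploidy = gm@ploidy, popMap = gm@popMap,
      chromLengths = gm@chromLengths, depth = NULL, minorFrac = NULL)
}

# Poisson (or overdispersed negative-binomial) window depths
.noisyDepth <- function(n, mean, overdispersion = 1) {
  if (overdispersion <= 1) return(rpois(n, mean))
  size <- mean / (overdispersion - 1)
  stats::rnbinom(n, size = size, mu = mean)
}

#' Generate coverage tracks with a planted PAR and planted CNV regions
#'
#' Emulates per-window read-depth tables: an autosomal baseline at
#' `meanDepth`, a male X at half depth outside a planted pseudoautosomal
#' region (full depth inside it), a female X at full depth, and a Y-like
#' chromosome carrying copy-number regions at specified fold-changes in a
#' target sample. Depths are Poisson-noised (negative binomial when
#' `overdispersion > 1`).
#'
#' @param seed Integer seed.
#' @param windowBp PAR-scan window width (default 10 kb).
#' @param meanDepth Expected autosomal per-window depth.
#' @param xLength,autoLength X / autosome lengths in bp.
#' @param parLength Planted PAR length at the start of the X (default
#'   2.36 Mb).
#' @param cnvChrom,cnvLength,cnvWindowBp,cnvStepBp Y-like chromosome used
#'   for the CNV scan, its length, and its sliding-window geometry
#'   (5 kb / 1 kb).
#' @param cnvRegions data.frame (start, end, fold) of planted expansions in
#'   the target sample (must not overlap).
#' @param overdispersion 1 = Poisson; > 1 adds extra-Poisson variance.
#' @param outDir Optional directory: per-sample TSV tracks plus a truth BED
#'   are written when given.
#' @return A list of tracks (`maleX`, `femaleX`, `autoMale`, `cnvTarget`,
#'   `cnvReference`), the `truth` list, and file paths when written.
#' @export
generateCoverageTracks <- function(seed, windowBp = 10000, meanDepth = 30,
                                   xLength = 2e7, autoLength = 2e7,
                                   parLength = 2.36e6,
                                   cnvChrom = "chrY", cnvLength = 1e7,
                                   cnvWindowBp = 5000, cnvStepBp = 1000,
                                   cnvRegions = data.frame(
                                     start = 4e6, end = 5.35e6, fold = 4),
                                   overdispersion = 1, outDir = NULL) {
  if (nrow(cnvRegions) > 1) {
    o <- order(cnvRegions$start)
    .check(all(cnvRegions$start[o][-1] >= cnvRegions$end[o][-nrow(cnvRegions)]),
           "planted CNV regions must not overlap")
  }
  set.seed(seed)
  xw <- .makeWindows(xLength, windowBp)
  inPar <- xw$start < parLength
  mk <- function(sample, chrom, w, mult) {
    data.frame(sample = sample, chrom = chrom, start = w$start, end = w$end,
               depth = .noisyDepth(nrow(w), meanDepth * mult,
                                   overdispersion))
  }
  maleX <- mk("male1", "chrX", xw, ifelse(inPar, 1, 0.5))
  femaleX <- mk("female1", "chrX", xw, 1)
  aw <- .makeWindows(autoLength, windowBp)
  autoMale <- mk("male1", "chr1", aw, 1)
  starts <- seq(0, cnvLength - cnvWindowBp, by = cnvStepBp)
  cw <- data.frame(start = starts, end = starts + cnvWindowBp)
  mid <- (cw$start + cw$end) / 2
  fold <- rep(1, nrow(cw))
  for (i in seq_len(nrow(cnvRegions)))
    fold[mid >= cnvRegions$start[i] & mid < cnvRegions$end[i]] <-
      cnvRegions$fold[i]
  cnvTarget <- mk("target1", cnvChrom, cw, 0.5 * fold)
  cnvReference <- mk("ref1", cnvChrom, cw, 0.5)
  truth <- list(seed = seed, parChrom = "chrX", parStart = 0,
                parEnd = parLength, cnvChrom = cnvChrom,
                cnvRegions = cnvRegions, meanDepth = meanDepth,
                windowBp = windowBp, cnvWindowBp = cnvWindowBp,
                cnvStepBp = cnvStepBp)
  out <- list(maleX = maleX, femaleX = femaleX, autoMale = autoMale,
              cnvTarget = cnvTarget, cnvReference = cnvReference,
              truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("maleX", "femaleX", "autoMale", "cnvTarget",
                 "cnvReference")) {
      p <- file.path(outDir, paste0(nm, ".tsv"))
      write.table(out[[nm]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$paths[[nm]] <- p
    }
    tb <- file.path(outDir, "truth.bed")
    writeBed(rbind(
      data.frame(chrom = "chrX", start = 0, end = parLength,
                 label = "PAR"),
      data.frame(chrom = cnvChrom, start = cnvRegions$start,
                 end = cnvRegions$end,
                 label = paste0("CNV_fold", cnvRegions$fold))), tb)
    out$paths$truth <- tb
  }
  out
}

# codon table helpers for CDS fixture construction: codons whose translation
# is a unique, unambiguous amino acid (no stops)
.senseCodons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)),
    character(1))
  codons[aa != "*"]
}

#' Generate per-gene CDS fixtures with planted fixed differences
#'
#' Builds one FASTA alignment per gene in which clade A and clade B share a
#' random stop-free coding sequence, differing only at `diffs[gene]`
#' planted positions where the two clades carry codons encoding different
#' amino acids. Genes flagged in `injectStop` additionally carry an
#' internal stop codon in one clade-A sample (and are therefore expected to
#' be excluded by the screen). A truth TSV records the planted counts.
#'
#' @param outDir Output directory.
#' @param seed Integer seed.
#' @param diffs Integer vector: planted fixed amino-acid differences per
#'   gene (its length sets the gene count). The default emulates the study
#'   scale: 13 genes with at least one difference (top genes with five and
#'   four), 15 without.
#' @param injectStop Logical vector (recycled): inject an internal stop in
#'   one clade-A sample of that gene.
#' @param nPerClade Samples per clade.
#' @param nCodons Gene length in codons.
#' @return Invisibly, a list with `files` (named FASTA paths), `truth`
#'   (data.frame), and `truthFile`.
#' @export
generateCdsFixtures <- function(outDir, seed,
                                diffs = c(5, 4, 2, 2, rep(1, 9),
                                          rep(0, 15)),
                                injectStop = c(rep(FALSE, length(diffs) - 2),
                                               TRUE, TRUE),
                                nPerClade = 2, nCodons = 120) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sense <- .senseCodons()
  aaOf <- function(cd) vapply(cd, function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x),
                                       no.init.codon = TRUE)),
    character(1))
  senseAa <- aaOf(sense)
  injectStop <- rep_len(injectStop, length(diffs))
  genes <- sprintf("gene%02d", seq_along(diffs))
  cladeA <- paste0("introgressed_", seq_len(nPerClade))
  cladeB <- paste0("ancestral_", seq_len(nPerClade))
  files <- character(0)
  truth <- list()
  for (i in seq_along(diffs)) {
    base <- sample(sense, nCodons, replace = TRUE)
    k <- diffs[i]
    .check(k < nCodons, "more planted differences than codons")
    posn <- if (k > 0) sort(sample(2:(nCodons - 1), k)) else integer()
    codA <- codB <- base
    for (p in posn) {
      aaHere <- aaOf(base[p])
      alt <- sample(sense[senseAa != aaHere], 1)
      codA[p] <- alt
    }
    seqs <- c(setNames(rep(paste(codA, collapse = ""), nPerClade), cladeA),
              setNames(rep(paste(codB, collapse = ""), nPerClade), cladeB))
    if (injectStop[i]) {
      stopPos <- sample(2:(nCodons - 1), 1)
      cod <- strsplit(seqs[cladeA[1]], "")[[1]]
      cod[(3 * stopPos - 2):(3 * stopPos)] <- c("T", "A", "A")
      seqs[cladeA[1]] <- paste(cod, collapse = "")
    }
    f <- file.path(outDir, paste0(genes[i], ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), f)
    files[genes[i]] <- f
    truth[[i]] <- data.frame(gene = genes[i], plantedDiffs = k,
                             positions = paste(posn, collapse = ","),
                             stopInjected = injectStop[i])
  }
  truth <- do.call(rbind, truth)
  truthFile <- file.path(outDir, "truth.tsv")
  write.table(truth, truthFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(files = files, truth = truth, truthFile = truthFile,
                 cladeA = cladeA, cladeB = cladeB))
}
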