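#' ABBACounts: frequency-weighted ABBA/BABA sums with jackknife blocks
#'
#' Holds the genome-wide frequency-weighted ABBA and BABA sums for a
#' (P1, P2, P3, outgroup) test together with their per-block decomposition
#' for the block jackknife.
#'
#' @slot abba,baba Genome-wide frequency-weighted sums.
#' @slot blockAbba,blockBaba Named per-block sums (totalling the global
#'   sums).
#' @slot nSitesUsed Number of sites contributing.
#' @slot nSkipped Sites skipped (outgroup missing/polymorphic or any
#'   population entirely missing).
#' @export
setClass("ABBACounts",
  representation(abba = "numeric", baba = "numeric",
                 blockAbba = "numeric", blockBaba = "numeric",
                 nSitesUsed = "integer", nSkipped = "integer"))

setValidity("ABBACounts", function(object) {
  msgs <- character()
  if (object@abba < 0 || object@baba < 0) msgs <- c(msgs, "sums must be >= 0")
  if (abs(sum(object@blockAbba) - object@abba) > 1e-8 * max(1, object@abba) ||
      abs(sum(object@blockBaba) - object@baba) > 1e-8 * max(1, object@baba))
    msgs <- c(msgs, "block sums must total the global sums")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ABBACounts", function(object) {
  cat(sprintf("ABBACounts: ABBA = %.4f, BABA = %.4f over %d sites (%d blocks)\n",
              object@abba, object@baba, object@nSitesUsed,
              length(object@blockAbba)))
  invisible(object)
})

#' Assign jackknife blocks to sites
#'
#' Either `nBlocks` equal-length genomic spans per chromosome (the
#' convention for real multi-chromosome data), or `nBlocks` contiguous
#' blocks over the genome as a whole — whole chromosomes/loci grouped in
#' order — which is the convention for simulated many-locus data.
#'
#' @param chrom,pos Site coordinates.
#' @param nBlocks Number of blocks (per chromosome, or total).
#' @param perChromosome If `TRUE`, split each chromosome into `nBlocks`
#'   equal-length spans; otherwise form `nBlocks` contiguous groups of whole
#'   chromosomes (falling back to equal spans when there are fewer
#'   chromosomes than blocks).
#' @param chromLengths Optional named lengths (defaults to the max observed
#'   position per chromosome).
#' @return Character vector of block labels, one per site.
#' @export
jackknifeBlocks <- function(chrom, pos, nBlocks = 20, perChromosome = FALSE,
                            chromLengths = NULL) {
  chroms <- unique(chrom)
  if (perChromosome || length(chroms) < nBlocks) {
    out <- character(length(chrom))
    nb <- if (perChromosome) nBlocks else ceiling(nBlocks / length(chroms))
    for (ch in chroms) {
      i <- chrom == ch
      len <- if (!is.null(chromLengths) && ch %in% names(chromLengths))
        chromLengths[[ch]] else max(pos[i])
      b <- pmin(nb, 1L + ((pos[i] - 1L) * nb) %/% max(len, 1))
      out[i] <- paste0(ch, ":", b)
    }
    out
  } else {
    grp <- setNames(pmin(nBlocks, 1L + ((seq_along(chroms) - 1L) * nBlocks) %/%
                           length(chroms)), chroms)
    paste0("block", grp[chrom])
  }
}

#' Frequency-weighted ABBA/BABA counts
#'
#' Per site, with derived-allele frequencies `p1, p2, p3, pO` in the four
#' populations (polarized so the outgroup carries the ancestral allele):
#' `ABBA += (1 - p1) p2 p3 (1 - pO)` and `BABA += p1 (1 - p2) p3 (1 - pO)`.
#' Sites where the outgroup is polymorphic or entirely missing, or where any
#' ingroup population is entirely missing, are skipped. Counts are
#' accumulated per jackknife block.
#'
#' @param gm A [GenotypeMatrix-class] (biallelic sites).
#' @param p1,p2,p3,outgroup Population names in `samplePopulations(gm)`.
#' @param blocks Either a per-site block label vector or the number of
#'   blocks handed to [jackknifeBlocks()].
#' @param perChromosome Passed to [jackknifeBlocks()] when `blocks` is a
#'   count.
#' @return An [ABBACounts-class].
#' @export
abbaBabaCounts <- function(gm, p1, p2, p3, outgroup, blocks = 20,
                           perChromosome = FALSE) {
  f1 <- .popFreq(gm, p1); f2 <- .popFreq(gm, p2)
  f3 <- .popFreq(gm, p3); fO <- .popFreq(gm, outgroup)
  if (length(blocks) == 1 && is.numeric(blocks))
    blocks <- jackknifeBlocks(gm@chrom, gm@pos, nBlocks = blocks,
                              perChromosome = perChromosome,
                              chromLengths = gm@chromLengths)
  use <- !is.nan(f1) & !is.nan(f2) & !is.nan(f3) &
    !is.nan(fO) & (fO == 0 | fO == 1)
  nSkip <- sum(!use)
  if (!any(use)) {
    warning("no usable sites: ABBA/BABA counts are zero")
    return(new("ABBACounts", abba = 0, baba = 0,
               blockAbba = setNames(numeric(), character()),
               blockBaba = setNames(numeric(), character()),
               nSitesUsed = 0L, nSkipped = as.integer(nSkip)))
  }
  flip <- use & fO == 1  # polarize on the outgroup allele
  for (nm in c("f1", "f2", "f3", "fO")) {
    v <- get(nm); v[flip] <- 1 - v[flip]; assign(nm, v)
  }
  abbaSite <- (1 - f1[use]) * f2[use] * f3[use] * (1 - fO[use])
  babaSite <- f1[use] * (1 - f2[use]) * f3[use] * (1 - fO[use])
  bl <- factor(blocks[use])
  blockAbba <- tapply(abbaSite, bl, sum)
  blockBaba <- tapply(babaSite, bl, sum)
  new("ABBACounts",
      abba = sum(abbaSite), baba = sum(babaSite),
      blockAbba = setNames(as.numeric(blockAbba), levels(bl)),
      blockBaba = setNames(as.numeric(blockBaba), levels(bl)),
      nSitesUsed = sum(use), nSkipped = as.integer(nSkip))
}

#' Patterson's D statistic
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`, in `[-1, 1]`. A zero denominator
#' yields `NA` with a warning (undefined, not zero).
#'
#' @param counts An [ABBACounts-class].
#' @return The D statistic.
#' @export
dStatistic <- function(counts) {
  denom <- counts@abba + counts@baba
  if (denom == 0) {
    warning("ABBA + BABA is zero: D is undefined")
    return(NA_real_)
  }
  (counts@abba - counts@baba) / denom
}

#' Block-jackknife standard error and Z-score for D
#'
#' Delete-one-block pseudovalues of D with
#' `SE = sqrt((n - 1) / n * sum((D_-i - mean(D_-))^2))` and `Z = D / SE`.
#' The conventional significance threshold is `Z > 3` in the direction of
#' excess P2-P3 sharing.
#'
#' @param counts An [ABBACounts-class] with at least two non-empty blocks.
#' @return A list with `d`, `se`, `z`, and `nBlocks`.
#' @export
blockJackknifeZ <- function(counts) {
  keep <- (counts@blockAbba + counts@blockBaba) > 0
  .check(sum(keep) >= 2, "need at least two non-empty jackknife blocks")
  a <- counts@blockAbba[keep]; b <- counts@blockBaba[keep]
  n <- length(a)
  d <- dStatistic(counts)
  dDel <- (counts@abba - a - (counts@baba - b)) /
    (counts@abba + counts@baba - a - b)
  se <- sqrt((n - 1) / n * sum((dDel - mean(dDel))^2))
  z <- if (se > 0) d / se else if (d == 0) 0 else {
    warning("jackknife SE is zero with non-zero D; Z reported as infinite")
    sign(d) * Inf
  }
  list(d = d, se = se, z = z, nBlocks = n)
}

#' Mask genotype calls by allele balance and depth; drop heterozygous Y sites
#'
#' Applies the per-call masks used ahead of all downstream statistics:
#' heterozygous calls whose minor-allele read fraction is below
#' `minMinorFrac` become missing; per-sample calls with depth below
#' `depthRange[1]` times or above `depthRange[2]` times the sample's
#' relevant mean depth become missing (boundaries retained); and on sex
#' chromosomes named in `hemizygousChroms`, any site heterozygous in any
#' sample is dropped for all samples. Mean depths are computed per sample
#' from the depth matrix: genome-wide over non-sex chromosomes, and
#' chromosome-wide for each sex chromosome.
#'
#' @param gm A [GenotypeMatrix-class] with `depth` and/or `minorFrac`
#'   metadata (an explicit error names a missing field its filter needs).
#' @param minMinorFrac Minor-allele read-fraction threshold for het calls.
#' @param depthRange Relative depth retention bounds (inclusive).
#' @param hemizygousChroms Chromosome names treated as X/Y: chromosome-wide
#'   mean depths, and (for those in `dropHetChroms`) het-site removal.
#' @param dropHetChroms Chromosomes (typically the Y) on which a site
#'   heterozygous in any sample is removed entirely.
#' @param meanDepths Optional named per-sample genome-wide mean depths to
#'   use instead of means computed from the depth matrix (the matrix at
#'   hand may be a small slice of the genome the means were estimated
#'   from). Chromosome-wide means for `hemizygousChroms` are always
#'   computed from the data.
#' @return A list with `matrix` (the filtered [GenotypeMatrix-class]) and
#'   `report` (calls/sites affected per filter).
#' @export
applySiteFilters <- function(gm, minMinorFrac = 0.25, depthRange = c(0.5, 2),
                             hemizygousChroms = character(),
                             dropHetChroms = character(),
                             meanDepths = NULL) {
  g <- gm@geno
  report <- c(hetLowBalanceMasked = 0L, depthMasked = 0L, yHetSitesDropped = 0L)
  if (!is.null(gm@minorFrac)) {
    het <- !is.na(g) & g == 1L & gm@ploidy == 2L
    mask <- het & !is.na(gm@minorFrac) & gm@minorFrac < minMinorFrac
    report["hetLowBalanceMasked"] <- sum(mask)
    g[mask] <- NA_integer_
  } else if (!is.null(gm@depth) || is.null(gm@minorFrac)) {
    if (is.null(gm@minorFrac) && is.null(gm@depth))
      stop("site filtering needs 'depth' and/or 'minorFrac' metadata; both are absent")
  }
  if (!is.null(gm@depth)) {
    isHemi <- gm@chrom %in% hemizygousChroms
    for (s in seq_len(ncol(g))) {
      d <- gm@depth[, s]
      meanAuto <- if (!is.null(meanDepths)) meanDepths[[colnames(g)[s]]]
        else mean(d[!isHemi], na.rm = TRUE)
      rel <- rep(meanAuto, length(d))
      for (ch in intersect(hemizygousChroms, unique(gm@chrom))) {
        i <- gm@chrom == ch
        rel[i] <- mean(d[i], na.rm = TRUE)
      }
      bad <- !is.na(d) & rel > 0 & (d < depthRange[1] * rel |
                                    d > depthRange[2] * rel)
      report["depthMasked"] <- report["depthMasked"] + sum(bad & !is.na(g[, s]))
      g[bad, s] <- NA_integer_
    }
  }
  keep <- rep(TRUE, nrow(g))
  if (length(dropHetChroms) && gm@ploidy == 2L) {
    onY <- gm@chrom %in% dropHetChroms
    anyHet <- rowSums(!is.na(g) & g == 1L) > 0
    drop <- onY & anyHet
    report["yHetSitesDropped"] <- sum(drop)
    keep <- !drop
  }
  sub <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  out <- new("GenotypeMatrix", geno = g[keep, , drop = FALSE],
             chrom = gm@chrom[keep], pos = gm@pos[keep], ploidy = gm@ploidy,
             popMap = gm@popMap, chromLengths = gm@chromLengths,
             depth = sub(gm@depth), minorFrac = sub(gm@minorFrac))
  list(matrix = out, report = report)
}

# internal window iterator: returns data.frame(chrom, start, end) 0-based
.windowGrid <- function(gm, windowBp) {
  chroms <- unique(gm@chrom)
  do.call(rbind, lapply(chroms, function(ch) {
    len <- if (ch %in% names(gm@chromLengths)) gm@chromLengths[[ch]] else
      max(gm@pos[gm@chrom == ch])
    w <- .makeWindows(len, windowBp)
    cbind(data.frame(chrom = ch, stringsAsFactors = FALSE), w)
  }))
}

#' Windowed f_d admixture-fraction statistic
#'
#' Martin et al.'s windowed estimator: per window,
#' `f_d = S(P1, P2, P3, O) / S(P1, P_D, P_D, O)` where
#' `S = sum(ABBA - BABA)` over sites and `P_D` is, per site, whichever of
#' P2/P3 has the higher derived-allele frequency. Windows with a
#' non-positive numerator are reported as 0; windows with a zero
#' denominator as `NA`.
#'
#' @inheritParams abbaBabaCounts
#' @param windowBp Window size in bp (0-based half-open windows).
#' @return data.frame (chrom, start, end, nSites, fd).
#' @export
fdWindows <- function(gm, p1, p2, p3, outgroup, windowBp = 10000) {
  .check(windowBp > 0, "windowBp must be > 0")
  f1 <- .popFreq(gm, p1); f2 <- .popFreq(gm, p2)
  f3 <- .popFreq(gm, p3); fO <- .popFreq(gm, outgroup)
  use <- !is.nan(f1) & !is.nan(f2) & !is.nan(f3) &
    !is.nan(fO) & (fO == 0 | fO == 1)
  flip <- use & fO == 1
  for (nm in c("f1", "f2", "f3", "fO")) {
    v <- get(nm); v[flip] <- 1 - v[flip]; assign(nm, v)
  }
  num <- den <- rep(NA_real_, length(f1))
  fd <- pmax(f2, f3)
  num[use] <- ((1 - f1) * f2 * f3 * (1 - fO) -
                 f1 * (1 - f2) * f3 * (1 - fO))[use]
  den[use] <- ((1 - f1) * fd * fd * (1 - fO) -
                 f1 * (1 - fd) * fd * (1 - fO))[use]
  wins <- .windowGrid(gm, windowBp)
  res <- lapply(seq_len(nrow(wins)), function(i) {
    sel <- which(gm@chrom == wins$chrom[i] & gm@pos > wins$start[i] &
                   gm@pos <= wins$end[i] & use)
    if (!length(sel)) return(c(0, NA_real_))
    S <- sum(num[sel]); Sd <- sum(den[sel])
    val <- if (Sd == 0) NA_real_ else if (S <= 0) 0 else S / Sd
    c(length(sel), val)
  })
  res <- do.call(rbind, res)
  data.frame(wins, nSites = res[, 1], fd = res[, 2], row.names = NULL)
}

#' Windowed pairwise nucleotide divergence (dXY)
#'
#' Average number of nucleotide differences per site between two
#' populations: per window, the sum over comparable sites of the mean
#' difference across all cross-population allele pairs, divided by the
#' number of comparable sites (sites genotyped in both populations,
#' including invariant sites). Missing data shrink the denominator; they
#' never inflate divergence.
#'
#' @param gm A [GenotypeMatrix-class] that retains invariant sites (or see
#'   `completeCoverage`).
#' @param popA,popB Population names.
#' @param windowBp Window size (default 50 kb, non-overlapping).
#' @param minSites Minimum comparable sites for a window value.
#' @param completeCoverage If `TRUE`, every position of each chromosome
#'   (from `chromLengths`) is treated as genotyped in all samples, so the
#'   denominator is the window width. Appropriate for simulated data with
#'   no missingness, where invariant sites are implicit.
#' @return data.frame (chrom, start, end, nSites, dxy).
#' @export
dxyWindows <- function(gm, popA, popB, windowBp = 50000, minSites = 100,
                       completeCoverage = FALSE) {
  .check(windowBp > 0, "windowBp must be > 0")
  ca <- .popCounts(gm, popA); cb <- .popCounts(gm, popB)
  comparable <- ca$called > 0 & cb$called > 0
  diff <- rep(NA_real_, nSites(gm))
  i <- comparable
  diff[i] <- (ca$derived[i] * (cb$called[i] - cb$derived[i]) +
                (ca$called[i] - ca$derived[i]) * cb$derived[i]) /
    (ca$called[i] * cb$called[i])
  if (completeCoverage)
    .check(length(gm@chromLengths) > 0,
           "completeCoverage requires chromLengths")
  wins <- .windowGrid(gm, windowBp)
  res <- lapply(seq_len(nrow(wins)), function(k) {
    sel <- which(gm@chrom == wins$chrom[k] & gm@pos > wins$start[k] &
                   gm@pos <= wins$end[k] & comparable)
    nComp <- if (completeCoverage) wins$end[k] - wins$start[k] else length(sel)
    if (nComp < minSites) return(c(nComp, NA_real_))
    c(nComp, sum(diff[sel]) / nComp)
  })
  res <- do.call(rbind, res)
  data.frame(wins, nSites = res[, 1], dxy = res[, 2], row.names = NULL)
}

#' Scale nucleotide divergence to coalescence time
#'
#' `t = (dXY / (2 mu)) * g`, in years.
#'
#' @param dxy Pairwise divergence per site (>= 0).
#' @param mu Mutation rate per bp per generation (> 0).
#' @param g Generation time in years (> 0).
#' @return Coalescence time in years (vectorized).
#' @export
#' @examples
#' coalescenceTimeFromDxy(9.64e-4, 4.82e-9, 10)  # 1e6 years
coalescenceTimeFromDxy <- function(dxy, mu, g) {
  .check(all(dxy >= 0, na.rm = TRUE), "dxy must be >= 0")
  .check(mu > 0 && g > 0, "mu and g must be > 0")
  (dxy / (2 * mu)) * g
}
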