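# Gene-tree simulation under a DemographicModel: structured coalescent with
# exact event scheduling at pulse/split/epoch boundaries (continuous-time
# exponential waiting between events; engine in src/coalescent.cpp).

# internal: lineage bookkeeping for a samples spec
# samples: named integer vector population -> number of individuals
.lineageSetup <- function(model, samples) {
  .check(all(names(samples) %in% names(model@populations)),
         "samples reference unknown populations")
  alive0 <- vapply(names(samples), function(p)
    .popSpan(model, p)["start"] == 0, logical(1))
  .check(all(alive0), "sampled populations must exist at time 0")
  perInd <- if (model@ploidyMode == "y_linked") 1L else 2L
  pops <- rep(names(samples), times = samples * perInd)
  labels <- unlist(lapply(names(samples), function(p) {
    n <- samples[[p]]
    if (perInd == 2L)
      paste0(p, "_", rep(seq_len(n), each = 2), c("a", "b"))
    else paste0(p, "_", seq_len(n))
  }))
  sampleIds <- unlist(lapply(names(samples), function(p)
    rep(paste0(p, "_", seq_len(samples[[p]])), each = perInd)))
  list(pops = pops, labels = labels, sampleIds = sampleIds, perInd = perInd)
}

# internal: parent/time arrays -> ape phylo with branch lengths in generations
.parentToPhylo <- function(parent, time, labels) {
  n <- length(labels)
  apeId <- function(node) ifelse(node < n, node + 1L, 3L * n - 1L - node)
  child <- which(parent >= 0) - 1L              # 0-based node ids
  edge <- cbind(apeId(parent[child + 1L]), apeId(child))
  len <- time[parent[child + 1L] + 1L] - time[child + 1L]
  tr <- list(edge = edge, edge.length = len, tip.label = labels,
             Nnode = n - 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "nodeTimes") <- time
  tr
}

#' Simulate one gene tree under a demographic model
#'
#' Backward-in-time structured coalescent: within a population of diploid
#' size Ne each lineage pair coalesces at rate `1/(2 Ne)` per generation
#' (Ne already quartered in `y_linked` mode); at an introgression pulse each
#' lineage in the destination independently relocates to the source with
#' probability phi; at a split, lineages in the derived population move to
#' the ancestral one. A diploid sample contributes two lineages in autosomal
#' mode and one in `y_linked` mode.
#'
#' @param model A [DemographicModel-class].
#' @param samples Named integer vector: population -> number of sampled
#'   individuals (populations must exist at time 0; >= 2 lineages total).
#' @param seed Optional integer seed.
#' @return An `ape::phylo` with branch lengths in generations, tip labels
#'   `<population>_<i>[a|b]`, and a `tipPopulations` attribute.
#' @export
#' @examples
#' m <- guenonModel()
#' tr <- simulateGeneTree(m, c(denti = 1, mitis = 1, macaque = 1), seed = 1)
simulateGeneTree <- function(model, samples, seed = NULL) {
  validObject(model)
  ls <- .lineageSetup(model, samples)
  .check(length(ls$pops) >= 2, "need at least two lineages in total")
  cm <- .compileModel(model)
  if (!is.null(seed)) {
    .check(is.finite(seed), "invalid seed")
    set.seed(seed)
  }
  sim <- .simTreesCpp(1L, unname(cm$popIndex[ls$pops]), cm$ne0, cm$events)
  tr <- .parentToPhylo(sim$parent[, 1], sim$time[, 1], ls$labels)
  attr(tr, "tipPopulations") <- setNames(ls$pops, ls$labels)
  tr
}

#' Overlay infinite-sites mutations on a gene tree
#'
#' Each branch receives `Poisson(length * mu * lengthBp)` mutations, each at
#' a distinct site; the derived allele is carried exactly by the leaves
#' descending from the mutated branch.
#'
#' @param tree An `ape::phylo` with branch lengths in generations.
#' @param lengthBp Locus length in bp (>= 0).
#' @param mu Mutation rate per bp per generation (>= 0).
#' @param seed Optional integer seed.
#' @return A 0/1 integer matrix (sites x leaves) of derived-allele
#'   indicators, with tip labels as column names.
#' @export
overlayMutations <- function(tree, lengthBp, mu, seed = NULL) {
  .check(mu >= 0 && lengthBp >= 0, "mu and lengthBp must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  tips <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) tips[[i]] <- i
  patterns <- list()
  # postorder: every child's tip set is complete before its edge is reached
  for (e in seq_len(nrow(tr$edge)))
    tips[[tr$edge[e, 1]]] <- c(tips[[tr$edge[e, 1]]], tips[[tr$edge[e, 2]]])
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    under <- tips[[child]]
    k <- rpois(1, tr$edge.length[e] * mu * lengthBp)
    if (k > 0) {
      row <- integer(n); row[under] <- 1L
      patterns <- c(patterns, rep(list(row), k))
    }
  }
  out <- if (length(patterns)) do.call(rbind, patterns) else
    matrix(integer(), ncol = n)
  colnames(out) <- tr$tip.label
  out
}

#' Simulate a multi-locus genotype matrix
#'
#' Simulates `lociCount` independent non-recombining genealogies under the
#' model, overlays infinite-sites mutations, and assembles the site patterns
#' into a [GenotypeMatrix-class]: diploid dosages by pairing the two haploid
#' lineages of each sample in autosomal mode, haploid dosages in `y_linked`
#' mode. Each locus becomes its own chromosome (`locus_00001`, ...) with
#' sites at distinct uniformly drawn positions. Deterministic given `seed`.
#'
#' @inheritParams simulateGeneTree
#' @param lociCount Number of independent loci.
#' @param lociLength Length of each locus in bp.
#' @param seed Integer seed.
#' @return A [GenotypeMatrix-class] with `chromLengths` set for every locus.
#' @export
simulateGenotypeMatrix <- function(model, lociCount, lociLength, samples,
                                   seed = NULL) {
  validObject(model)
  .check(lociCount > 0 && lociLength > 0, "lociCount and lociLength must be > 0")
  ls <- .lineageSetup(model, samples)
  cm <- .compileModel(model)
  if (!is.null(seed)) set.seed(seed)
  sim <- .simPatternsCpp(as.integer(lociCount), unname(cm$popIndex[ls$pops]),
                         cm$ne0, cm$events, model@mu * lociLength)
  pat <- sim$patterns
  colnames(pat) <- ls$labels
  if (ls$perInd == 2L) {
    ids <- unique(ls$sampleIds)
    geno <- vapply(ids, function(sid)
      rowSums(pat[, ls$sampleIds == sid, drop = FALSE]), numeric(nrow(pat)))
    if (nrow(pat) == 1) geno <- matrix(geno, nrow = 1,
                                       dimnames = list(NULL, ids))
    if (nrow(pat) == 0) geno <- matrix(integer(), ncol = length(ids),
                                       dimnames = list(NULL, ids))
  } else {
    geno <- pat
  }
  storage.mode(geno) <- "integer"
  chrom <- sprintf("locus_%05d", sim$locus)
  # distinct positions per locus (infinite sites on a finite grid)
  pos <- integer(length(sim$locus))
  for (idx in split(seq_along(sim$locus), sim$locus)) {
    k <- length(idx)
    pos[idx] <- sort(sample.int(lociLength, min(k, lociLength)))[seq_len(k)]
  }
  popMap <- setNames(ls$pops[!duplicated(ls$sampleIds)],
                     unique(ls$sampleIds))
  if (ls$perInd == 1L) popMap <- setNames(ls$pops, ls$labels)
  lens <- setNames(rep(lociLength, lociCount),
                   sprintf("locus_%05d", seq_len(lociCount)))
  GenotypeMatrix(geno, chrom = chrom, pos = pos, popMap = popMap,
                 ploidy = ls$perInd, chromLengths = lens)
}

#' Simulate multi-locus ABBA/BABA counts without materializing genotypes
#'
#' Streaming equivalent of [simulateGenotypeMatrix()] followed by
#' [abbaBabaCounts()]: per-locus frequency-weighted ABBA/BABA sums are
#' accumulated inside the simulation engine, so very large locus counts fit
#' in constant memory. Under the same seed the result is identical to the
#' two-step path (the engines consume the random stream in the same order).
#'
#' @inheritParams simulateGenotypeMatrix
#' @param p1,p2,p3,outgroup Population names for the test.
#' @param nBlocks Number of jackknife blocks (contiguous groups of whole
#'   loci).
#' @return An [ABBACounts-class].
#' @export
simulateAbbaCounts <- function(model, lociCount, lociLength, samples,
                               p1, p2, p3, outgroup, nBlocks = 20,
                               seed = NULL) {
  validObject(model)
  ls <- .lineageSetup(model, samples)
  cm <- .compileModel(model)
  role <- rep(-1L, length(ls$pops))
  for (g in seq_along(c(p1, p2, p3, outgroup)))
    role[ls$pops == c(p1, p2, p3, outgroup)[g]] <- g - 1L
  if (!is.null(seed)) set.seed(seed)
  res <- .abbaLociCpp(as.integer(lociCount), unname(cm$popIndex[ls$pops]),
                      cm$ne0, cm$events, model@mu * lociLength, role)
  block <- 1L + ((seq_len(lociCount) - 1L) * nBlocks) %/% lociCount
  lab <- sprintf("block%02d", sort(unique(block)))
  new("ABBACounts",
      abba = sum(res$abba), baba = sum(res$baba),
      blockAbba = setNames(as.numeric(tapply(res$abba, block, sum)), lab),
      blockBaba = setNames(as.numeric(tapply(res$baba, block, sum)), lab),
      nSitesUsed = as.integer(sum(res$nUsed)),
      nSkipped = as.integer(sum(res$nSkipped)))
}

# internal: is the tip set `target` (0-based leaf ids) an exclusive clade?
.isClade <- function(parent, nLeaves, target) {
  m <- length(parent)
  cntAll <- c(rep(1L, nLeaves), rep(0L, m - nLeaves))
  cntS <- integer(m)
  cntS[target + 1L] <- 1L
  for (i in seq_len(m - 1L)) {      # children created before parents
    p <- parent[i] + 1L
    cntAll[p] <- cntAll[p] + cntAll[i]
    cntS[p] <- cntS[p] + cntS[i]
  }
  k <- length(target)
  mrca <- which(cntS == k)[1]       # earliest node containing all of S
  cntAll[mrca] == k
}

#' Monophyly frequency of a taxon pair under the model
#'
#' Simulates `nSims` gene trees and reports the fraction in which the
#' sampled lineages of `taxonA` and `taxonB` form an exclusive clade, with a
#' Clopper-Pearson binomial confidence interval.
#'
#' @inheritParams simulateGeneTree
#' @param taxonA,taxonB Population names (must be sampled).
#' @param nSims Number of simulated genealogies (>= 1).
#' @param conf Confidence level.
#' @return A list with `frequency`, `ci`, `nSims`.
#' @export
monophylyFrequency <- function(model, taxonA, taxonB, samples, nSims = 1000,
                               seed = NULL, conf = 0.95) {
  .check(nSims >= 1, "nSims must be >= 1")
  .check(all(c(taxonA, taxonB) %in% names(samples)) &&
           samples[[taxonA]] > 0 && samples[[taxonB]] > 0,
         "both taxa must be sampled")
  ls <- .lineageSetup(model, samples)
  cm <- .compileModel(model)
  if (!is.null(seed)) set.seed(seed)
  sim <- .simTreesCpp(as.integer(nSims), unname(cm$popIndex[ls$pops]),
                      cm$ne0, cm$events)
  n <- length(ls$pops)
  target <- which(ls$pops %in% c(taxonA, taxonB)) - 1L
  hits <- vapply(seq_len(nSims), function(s)
    .isClade(sim$parent[, s], n, target), logical(1))
  ci <- stats::binom.test(sum(hits), nSims, conf.level = conf)$conf.int
  list(frequency = mean(hits), ci = c(lower = ci[1], upper = ci[2]),
       nSims = nSims)
}

#' Donor-ancestry linkage profile along the pseudoautosomal region
#'
#' For each distance bin along a PAR of `parLengthBp`, runs the two-locus
#' forward model of [simulateYParLinkage()] with per-generation
#' recombination probability
#' `parRecMultiplier * autosomalRecRate * distance` and reports the final
#' donor-PAR-ancestry frequency among donor-Y carriers and overall. With a
#' tenfold or higher recombination multiplier the distal-end donor-ancestry
#' fraction approaches the autosomal expectation (`p0 / 2` under exclusively
#' male migration).
#'
#' @param model A [DemographicModel-class]; its mitis -> denti pulse supplies
#'   the introgression proportion `p0` unless `p0` is given.
#' @param parRecMultiplier PAR recombination rate as a multiple of the
#'   autosomal rate (> 0; the study used 1, 10 and 20).
#' @param nSims Replicate simulations averaged per bin (single runs are
#'   bistable once the donor-Y PAR pool coalesces, so the expectation needs
#'   replicate averaging; runs that lose the donor Y are discarded).
#' @param nYCopies Number of Y copies in the recipient population.
#' @param maxGens Generations of decay simulated per bin.
#' @param parLengthBp PAR length (150 kb in the study design).
#' @param nBins Number of distance bins.
#' @param autosomalRecRate Autosomal recombination rate per bp per
#'   generation.
#' @param p0 Introgression proportion (initial donor-Y frequency).
#' @param seed Optional integer seed.
#' @return data.frame with one row per bin: `binStart`, `binEnd`,
#'   `recProb`, `donorParAmongDonorY`, `donorParOverall`, and
#'   `autosomalExpectation`.
#' @export
parLinkageProfile <- function(model, parRecMultiplier, nSims = 20,
                              nYCopies = 100000,
                              maxGens = 10000, parLengthBp = 150000,
                              nBins = 15, autosomalRecRate = 4.48e-9,
                              p0 = NULL, seed = NULL) {
  .check(parRecMultiplier > 0, "parRecMultiplier must be > 0")
  if (is.null(p0)) {
    pu <- model@pulses
    i <- which(pu$dest == "denti" & pu$source == "mitis")
    .check(length(i) == 1, "model has no mitis -> denti pulse; supply p0")
    p0 <- pu$phi[i]
    if (model@ploidyMode == "autosomal") p0 <- min(1, 2 * p0)
  }
  bins <- .makeWindows(parLengthBp, ceiling(parLengthBp / nBins))
  mid <- (bins$start + bins$end) / 2
  recProb <- pmin(1, parRecMultiplier * autosomalRecRate * mid)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_along(mid), function(b) {
    finals <- vapply(seq_len(nSims), function(s) {
      # discard runs in which the donor Y is lost (as the study design does)
      for (attempt in 1:50) {
        tr <- simulateYParLinkage(nYCopies, p0, recProb[b],
                                  maxGens = maxGens)
        last <- tr[nrow(tr), ]
        if (last$freqDonorY > 0) break
      }
      c(last$donorParAmongDonorY, last$donorParOverall)
    }, numeric(2))
    rowMeans(finals, na.rm = TRUE)  # NA: every attempt lost the donor Y
  })
  res <- do.call(rbind, res)
  data.frame(binStart = bins$start, binEnd = bins$end, recProb = recProb,
             donorParAmongDonorY = res[, 1], donorParOverall = res[, 2],
             autosomalExpectation = p0 / 2)
}
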