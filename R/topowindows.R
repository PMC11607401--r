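# Sliding-window phylogenetic scan: per-window distance matrices, canonical
# neighbor-joining, and classification of windows matching the
# introgressed-Y topology (focal taxon nested inside the donor group).

#' Pairwise distance matrix for a genotype window
#'
#' Computes per-pair mean per-site allelic difference (expected mismatch
#' between one allele drawn from each sample: `p_i (1 - p_j) + p_j (1 -
#' p_i)` with `p = dosage / ploidy`), over sites where both samples are
#' genotyped, optionally Jukes-Cantor corrected
#' (`-(3/4) log(1 - 4 p / 3)`).
#'
#' @param geno Dosage matrix (sites x samples) for one window; invariant
#'   rows participate in the denominator.
#' @param ploidy 1 or 2.
#' @param model `"p_distance"` or `"jc69"`.
#' @return Symmetric numeric matrix with zero diagonal; `NA` where a pair
#'   has no comparable site. JC69 distances at `p >= 0.75` raise a
#'   saturation error.
#' @export
windowDistanceMatrix <- function(geno, ploidy = 2L,
                                 model = c("p_distance", "jc69")) {
  model <- match.arg(model)
  .check(ncol(geno) >= 3, "need at least three sequences")
  p <- geno / ploidy
  n <- ncol(geno)
  D <- matrix(0, n, n, dimnames = list(colnames(geno), colnames(geno)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(p[, i]) & !is.na(p[, j])
      if (!any(ok)) {
        D[i, j] <- D[j, i] <- NA
        next
      }
      d <- mean(p[ok, i] * (1 - p[ok, j]) + p[ok, j] * (1 - p[ok, i]))
      if (model == "jc69") {
        if (d >= 0.75)
          stop("pairwise distance saturated under JC69 (p >= 0.75)")
        d <- -0.75 * log(1 - 4 * d / 3)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor joining with a deterministic tie-break
#'
#' Canonical Saitou-Nei NJ on a symmetric distance matrix. Ties in the
#' Q-criterion are broken by the lexicographically lowest pair of current
#' node indices (original taxon order first). Negative branch lengths are
#' clamped to zero with the length transferred to the sister branch.
#'
#' @param D Symmetric distance matrix with at least three taxa and no
#'   missing entries.
#' @return An unrooted `ape::phylo`.
#' @export
neighborJoining <- function(D) {
  .check(is.matrix(D) && nrow(D) == ncol(D) && nrow(D) >= 3,
         "D must be a square matrix with n >= 3")
  .check(!anyNA(D), "distance matrix has missing entries")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  nodes <- as.list(labels)          # newick fragment per active node
  idx <- seq_len(nrow(D))           # creation index per active node
  nextIdx <- nrow(D) + 1
  while (length(nodes) > 3) {
    r <- length(nodes)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= abs(qmin) * 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(idx[cand[, 1]], idx[cand[, 2]])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
                c(newD[keep], 0))
    nodes <- c(nodes[keep], sprintf("(%s:%.10g,%s:%.10g)",
                                    nodes[[i]], vi, nodes[[j]], vj))
    idx <- c(idx[keep], nextIdx); nextIdx <- nextIdx + 1
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[[1]], v[1], nodes[[2]], v[2], nodes[[3]], v[3])
  ape::read.tree(text = txt)
}

# internal: monophyly of a tip set on a rooted tree
.tipsMono <- function(tree, tips) {
  if (length(tips) <= 1) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Classify one window tree against the introgressed-Y topology
#'
#' Roots the tree on the outgroup, then tests the three clade conditions
#' that define a Y-like window: the focal taxon nested inside a
#' monophyletic donor-group clade, sister to the donor species, with the
#' focal taxon's own group (excluding it) monophyletic. `species_like`
#' requires the focal taxon's own group (including it) to be monophyletic
#' and, when `speciesSister` is given, the focal taxon sister to it.
#'
#' @param tree An unrooted `ape::phylo` whose tips are sample names.
#' @param taxa data.frame with columns `sample`, `species`, `group`
#'   covering every tip.
#' @param focal Focal species (e.g. the Y-introgressed lineage).
#' @param donorSpecies Donor species within the donor group.
#' @param outgroup Outgroup species used for rooting.
#' @param speciesSister Optional species-tree sister of the focal species.
#' @return A list with `label` (`"y_like"`, `"species_like"`, `"other"` or
#'   `"unresolved"`) and `tests` (named logicals).
#' @export
classifyWindowTopology <- function(tree, taxa, focal, donorSpecies,
                                   outgroup, speciesSister = NULL) {
  .check(all(tree$tip.label %in% taxa$sample), "taxa must cover every tip")
  .check(all(c(focal, donorSpecies, outgroup) %in% taxa$species),
         "focal, donorSpecies and outgroup must appear in taxa$species")
  tipsOf <- function(species) taxa$sample[taxa$species %in% species &
                                            taxa$sample %in% tree$tip.label]
  ogTips <- tipsOf(outgroup)
  .check(length(ogTips) > 0, "outgroup tips missing from tree")
  rooted <- tryCatch(
    ape::root(tree, outgroup = ogTips, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted))
    return(list(label = "unresolved", tests = c(rootable = FALSE)))
  donorGroup <- unique(taxa$group[taxa$species == donorSpecies])
  focalGroup <- unique(taxa$group[taxa$species == focal])
  donorGroupSpecies <- unique(taxa$species[taxa$group == donorGroup])
  focalTips <- tipsOf(focal)
  tests <- c(
    donorCladeWithFocal = .tipsMono(rooted, c(tipsOf(donorGroupSpecies),
                                              focalTips)),
    focalSisterToDonor = .tipsMono(rooted, c(focalTips,
                                             tipsOf(donorSpecies))) &&
      .tipsMono(rooted, focalTips),
    ownGroupExclFocalMono = .tipsMono(
      rooted, tipsOf(setdiff(unique(taxa$species[taxa$group == focalGroup]),
                             focal))))
  if (all(tests))
    return(list(label = "y_like", tests = tests))
  ownInclMono <- .tipsMono(
    rooted, tipsOf(unique(taxa$species[taxa$group == focalGroup])))
  sisterOk <- if (is.null(speciesSister)) TRUE else
    .tipsMono(rooted, c(focalTips, tipsOf(speciesSister))) &&
      .tipsMono(rooted, focalTips)
  if (ownInclMono && sisterOk)
    return(list(label = "species_like",
                tests = c(tests, ownGroupInclFocalMono = ownInclMono)))
  list(label = "other", tests = tests)
}

#' Sliding-window topology scan over a genotype matrix
#'
#' Builds a distance matrix and NJ tree in non-overlapping windows,
#' classifies each against the introgressed-Y topology, and merges adjacent
#' `y_like` windows into regions. Windows with more than `maxMissing`
#' missing calls, fewer than `minVariableSites` variable sites, or an
#' incomputable tree are `unresolved`.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param taxa data.frame (sample, species, group) covering all samples.
#' @param focal,donorSpecies,outgroup,speciesSister Passed to
#'   [classifyWindowTopology()].
#' @param windowBp Window size (default 10 kb).
#' @param minVariableSites,maxMissing Data-sufficiency thresholds.
#' @param distModel Distance model for [windowDistanceMatrix()].
#' @return A list with `windows` (data.frame chrom, start, end, nSites,
#'   class), `regions` (merged `y_like` spans), and `summary` (class
#'   counts).
#' @export
scanGenomeTopology <- function(gm, taxa, focal, donorSpecies, outgroup,
                               speciesSister = NULL, windowBp = 10000,
                               minVariableSites = 20, maxMissing = 0.5,
                               distModel = "p_distance") {
  wins <- .windowGrid(gm, windowBp)
  cls <- character(nrow(wins))
  nSites <- integer(nrow(wins))
  for (k in seq_len(nrow(wins))) {
    sel <- which(gm@chrom == wins$chrom[k] & gm@pos > wins$start[k] &
                   gm@pos <= wins$end[k])
    g <- gm@geno[sel, , drop = FALSE]
    variable <- sum(apply(g, 1, function(r) {
      r <- r[!is.na(r)]; length(r) > 0 && length(unique(r)) > 1
    }))
    nSites[k] <- length(sel)
    if (variable < minVariableSites ||
        (length(g) && mean(is.na(g)) > maxMissing)) {
      cls[k] <- "unresolved"
      next
    }
    label <- tryCatch({
      D <- windowDistanceMatrix(g, ploidy = gm@ploidy, model = distModel)
      if (anyNA(D)) "unresolved" else {
        tr <- neighborJoining(D)
        classifyWindowTopology(tr, taxa, focal, donorSpecies, outgroup,
                               speciesSister)$label
      }
    }, error = function(e) "unresolved")
    cls[k] <- label
  }
  windows <- data.frame(wins, nSites = nSites, class = cls,
                        row.names = NULL)
  regions <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    r <- rle(w$class == "y_like")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      regions[[length(regions) + 1]] <- data.frame(
        chrom = ch, start = w$start[starts[i]], end = w$end[ends[i]],
        nWindows = r$lengths[i])
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               nWindows = integer())
  list(windows = windows, regions = regions,
       summary = table(factor(cls, levels = c("y_like", "species_like",
                                              "other", "unresolved"))))
}
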