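# shared fixture builders (everything generated in code; no stored data)

# three-population ((A,B),C) model with a T-generation internal branch over
# ancestral size ne; haploid sampling so closed-form ILS results apply
ilsModel <- function(ne = 1e4, tSplit = 1e4, tRoot = 3e4) {
  DemographicModel(
    c(A = ne, B = ne, C = ne, AB = ne, ABC = ne),
    splits = data.frame(time = c(tSplit, tSplit, tRoot, tRoot),
                        derived = c("A", "B", "AB", "C"),
                        ancestral = c("AB", "AB", "ABC", "ABC")),
    mu = 1e-8, genTime = 10, ploidyMode = "y_linked")
}

# small diploid dosage matrix with coordinates, for window statistics
toyMatrix <- function(geno, chrom = "chr1", posStep = 10, popMap,
                      ploidy = 2L, chromLength = NULL) {
  n <- nrow(geno)
  pos <- seq(posStep, by = posStep, length.out = n)
  lens <- if (is.null(chromLength)) NULL else
    setNames(chromLength, unique(chrom))
  GenotypeMatrix(geno, chrom = rep_len(chrom, n), pos = pos,
                 popMap = popMap, ploidy = ploidy, chromLengths = lens)
}

# taxon table for the six-tip guenon topology fixtures
guenonTaxa <- function(samples) {
  species <- sub("_[0-9]+[ab]?$", "", samples)
  grp <- c(denti = "mona", wolfi = "mona", pogonias = "mona",
           mona = "mona", neglectus = "neglectus", cephus = "cephus",
           nictitans = "mitis_group", mitis = "mitis_group",
           macaque = "outgroup")
  data.frame(sample = samples, species = species,
             group = unname(grp[species]))
}

# brute-force frequency-weighted ABBA/BABA oracle over per-site frequencies
bruteAbba <- function(f1, f2, f3, fO) {
  abba <- baba <- 0
  for (s in seq_along(f1)) {
    p <- c(f1[s], f2[s], f3[s], fO[s])
    if (any(is.na(p)) || (p[4] > 0 && p[4] < 1)) next
    if (p[4] == 1) p <- 1 - p
    abba <- abba + (1 - p[1]) * p[2] * p[3] * (1 - p[4])
    baba <- baba + p[1] * (1 - p[2]) * p[3] * (1 - p[4])
  }
  c(abba = abba, baba = baba)
}
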