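test_that("window distances follow p-distance and JC69 formulas", {
  g <- matrix(0L, 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  g[1:2, 2] <- 1L
  D <- windowDistanceMatrix(g, ploidy = 1L)
  expect_equal(D["a", "b"], 0.02)
  expect_equal(D["a", "c"], 0)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  # JC69 of p = 0.1 -> 0.1073 (4 s.f.)
  g2 <- matrix(0L, 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  g2[1:10, 2] <- 1L
  Dj <- windowDistanceMatrix(g2, ploidy = 1L, model = "jc69")
  expect_equal(round(Dj["a", "b"], 4), 0.1073)
  # saturation is an error under JC69
  g3 <- matrix(0L, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  g3[1:9, 2] <- 1L
  expect_error(windowDistanceMatrix(g3, ploidy = 1L, model = "jc69"),
               "saturated")
  # a pair with no comparable sites is NA
  g4 <- matrix(c(0L, NA, 0L), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  g4 <- rbind(g4, c(NA, 0L, 0L))
  expect_true(is.na(windowDistanceMatrix(g4, ploidy = 1L)["a", "b"]))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    tr0 <- ape::rtree(n)
    D <- cophenetic(tr0)
    nj <- neighborJoining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), nj)), 0)
    # and agrees with the field-standard implementation on topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(D), nj)), 0)
    # four-point condition: reconstructed path lengths match the input
    expect_equal(cophenetic(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-6)
  }
  # three taxa: the single unrooted topology with exact branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighborJoining(D3)
  expect_equal(sort(t3$tip.label), c("a", "b", "c"))
  expect_equal(sum(t3$edge.length), (3 + 4 + 5) / 2)
  # star-like equal distances resolve deterministically via the tie-break
  Ds <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Ds) <- 0
  s1 <- ape::write.tree(neighborJoining(Ds))
  s2 <- ape::write.tree(neighborJoining(Ds))
  expect_identical(s1, s2)
  expect_error(neighborJoining(matrix(0, 2, 2)), "n >= 3")
  Dna <- D3; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(neighborJoining(Dna), "missing")
})

test_that("topology classification distinguishes Y-like from species-like trees", {
  samples <- c("denti_1", "wolfi_1", "pogonias_1", "mitis_1",
               "nictitans_1", "macaque_1")
  taxa <- guenonTaxa(samples)
  yTree <- ape::read.tree(text = paste0(
    "(((denti_1:1,mitis_1:1):1,nictitans_1:2):2,",
    "((wolfi_1:1,pogonias_1:1):3,macaque_1:5):1);"))
  res <- classifyWindowTopology(yTree, taxa, "denti", "mitis", "macaque",
                                speciesSister = "wolfi")
  expect_equal(res$label, "y_like")
  expect_true(all(res$tests))
  spTree <- ape::read.tree(text = paste0(
    "((((denti_1:1,wolfi_1:1):1,pogonias_1:2):2,",
    "(mitis_1:1,nictitans_1:1):2):1,macaque_1:5);"))
  expect_equal(classifyWindowTopology(spTree, taxa, "denti", "mitis",
                                      "macaque", "wolfi")$label,
               "species_like")
  # focal inside the donor group but not sister to the donor: not y_like
  partial <- ape::read.tree(text = paste0(
    "(((denti_1:1,nictitans_1:1):1,mitis_1:2):2,",
    "((wolfi_1:1,pogonias_1:1):3,macaque_1:5):1);"))
  expect_false(classifyWindowTopology(partial, taxa, "denti", "mitis",
                                      "macaque", "wolfi")$label == "y_like")
  expect_error(classifyWindowTopology(yTree, taxa[-1, ], "denti", "mitis",
                                      "macaque"), "cover")
})

# build a haploid matrix with species-tree signal everywhere except
# donor-copied windows where denti duplicates the mitis sequence
plantedScanMatrix <- function(nWindows = 6, donorWindows = 3,
                              sitesPerWindow = 80, seed = 19) {
  set.seed(seed)
  samples <- c("denti_1", "wolfi_1", "pogonias_1", "mitis_1",
               "nictitans_1", "macaque_1")
  n <- nWindows * sitesPerWindow
  geno <- matrix(0L, n, 6, dimnames = list(NULL, samples))
  win <- rep(seq_len(nWindows), each = sitesPerWindow)
  for (i in seq_len(n)) {
    if (win[i] %in% donorWindows) {
      # denti is a copy of mitis: every mitis variant is shared with denti
      patt <- sample(c("mitis3", "mitis2", "mona2", "w", "p", "n"), 1)
      cols <- switch(patt, mitis3 = c(1, 4, 5), mitis2 = c(1, 4),
                     mona2 = c(2, 3), w = 2, p = 3, n = 5)
    } else {
      patt <- sample(c("mona3", "dw", "mitis2", "d", "w", "p", "m", "n"), 1)
      cols <- switch(patt, mona3 = c(1, 2, 3), dw = c(1, 2),
                     mitis2 = c(4, 5), d = 1, w = 2, p = 3, m = 4, n = 5)
    }
    geno[i, cols] <- 1L
  }
  pos <- unlist(lapply(seq_len(nWindows), function(w)
    sort(sample.int(100, sitesPerWindow)) + (w - 1) * 100))
  GenotypeMatrix(geno, chrom = rep("chr1", n), pos = pos,
                 popMap = setNames(sub("_1", "", samples), samples),
                 ploidy = 1L, chromLengths = c(chr1 = nWindows * 100))
}

test_that("the genome scan finds exactly the planted donor-copied windows", {
  gm <- plantedScanMatrix(nWindows = 6, donorWindows = c(2, 5))
  taxa <- guenonTaxa(colnames(genotypes(gm)))
  sc <- scanGenomeTopology(gm, taxa, "denti", "mitis", "macaque", "wolfi",
                           windowBp = 100, minVariableSites = 20)
  expect_equal(sc$windows$class[c(2, 5)], c("y_like", "y_like"))
  expect_true(all(sc$windows$class[c(1, 3, 4, 6)] == "species_like"))
  expect_equal(nrow(sc$regions), 2)
  # adjacent y_like windows merge into one region
  gm2 <- plantedScanMatrix(nWindows = 6, donorWindows = c(2, 3))
  sc2 <- scanGenomeTopology(gm2, taxa, "denti", "mitis", "macaque", "wolfi",
                            windowBp = 100, minVariableSites = 20)
  expect_equal(nrow(sc2$regions), 1)
  expect_equal(sc2$regions$nWindows, 2)
  # zero-variant matrix: all unresolved
  gm0 <- GenotypeMatrix(matrix(0L, 50, 6,
                               dimnames = list(NULL, taxa$sample)),
                        chrom = rep("chr1", 50), pos = 1:50,
                        popMap = setNames(taxa$species, taxa$sample),
                        ploidy = 1L, chromLengths = c(chr1 = 100))
  sc0 <- scanGenomeTopology(gm0, taxa, "denti", "mitis", "macaque", "wolfi",
                            windowBp = 100)
  expect_true(all(sc0$windows$class == "unresolved"))
  # classes invariant under sample-order permutation
  perm <- c(4, 1, 6, 2, 5, 3)
  gmP <- gm[, perm]
  scP <- scanGenomeTopology(gmP, taxa, "denti", "mitis", "macaque", "wolfi",
                            windowBp = 100, minVariableSites = 20)
  expect_equal(scP$windows$class, sc$windows$class)
})
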