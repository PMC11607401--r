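test_that("pairwise coalescence times match the single-population expectation", {
  m <- DemographicModel(c(A = 1e4), mu = 1e-8, genTime = 10)
  set.seed(101)
  tm <- replicate(2000, {
    tr <- simulateGeneTree(m, c(A = 1))  # one diploid = two lineages
    max(attr(tr, "nodeTimes"))
  })
  # E[TMRCA] = 2 Ne, SD = 2 Ne for a sample of two
  se <- 2e4 / sqrt(2000)
  expect_lt(abs(mean(tm) - 2e4), 3 * se)
  tr <- simulateGeneTree(m, c(A = 2), seed = 1)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 4)
  expect_true(all(tr$edge.length >= 0))
  expect_true(all(is.finite(attr(tr, "nodeTimes"))))
})

test_that("three-taxon discordance matches the ILS closed form", {
  # ((A,B),C) with internal branch T = 2e4 over Ne = 1e4:
  # each discordant topology has frequency (1/3) exp(-T / (2 Ne))
  m <- ilsModel(ne = 1e4, tSplit = 1e4, tRoot = 3e4)
  expected <- (1 / 3) * exp(-1)
  f <- monophylyFrequency(m, "A", "C", c(A = 1, B = 1, C = 1),
                          nSims = 4000, seed = 7)
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(f$frequency - expected), 3 * se)
  # concordant topology: 1 - (2/3) exp(-T/(2Ne))
  fAB <- monophylyFrequency(m, "A", "B", c(A = 1, B = 1, C = 1),
                            nSims = 4000, seed = 8)
  expAB <- 1 - (2 / 3) * exp(-1)
  expect_lt(abs(fAB$frequency - expAB), 3 * sqrt(expAB * (1 - expAB) / 4000))
})

test_that("a phi = 1 pulse relocates every destination lineage", {
  # without the pulse, the A and B lineages can only meet at the deep root;
  # with phi = 1 at t = 100, the A lineage joins B's tiny population and
  # coalesces almost immediately
  m <- DemographicModel(
    c(A = 1e5, B = 100, R = 1e5),
    splits = data.frame(time = c(1e6, 1e6), derived = c("A", "B"),
                        ancestral = "R"),
    pulses = data.frame(time = 100, source = "B", dest = "A", phi = 1),
    ploidyMode = "y_linked")
  set.seed(3)
  tm <- replicate(200, max(attr(simulateGeneTree(
    m, c(A = 1, B = 1)), "nodeTimes")))
  expect_true(all(tm < 1e6))       # certain relocation: never the deep root
  expect_gt(mean(tm < 100 + 20 * 200), 0.95)
})

test_that("mutation overlay matches Watterson's expectation and edge cases", {
  m <- DemographicModel(c(A = 1e4), mu = 1e-8, genTime = 10)
  tr <- simulateGeneTree(m, c(A = 1), seed = 5)
  expect_equal(nrow(overlayMutations(tr, 1e5, 0)), 0)   # mu = 0, no sites
  set.seed(42)
  S <- replicate(400, {
    tr <- simulateGeneTree(m, c(A = 1))
    nrow(overlayMutations(tr, 1e5, 1e-8))
  })
  # E[S] = 2 E[TMRCA] mu L = 40 for n = 2; Var[S] inflated by TMRCA variance
  expect_lt(abs(mean(S) - 40), 3 * sd(S) / sqrt(400))
  # with two leaves every branch is pendant: each mutation marks one leaf
  pat <- overlayMutations(tr, 1e7, 1e-6, seed = 9)
  expect_gt(nrow(pat), 0)
  expect_true(all(rowSums(pat) == 1))
})

test_that("genotype simulation is deterministic and pattern-consistent", {
  m <- guenonModel(phi3 = 0.01)
  samples <- c(wolfi = 1, denti = 1, mitis = 1, macaque = 1)
  g1 <- simulateGenotypeMatrix(m, 30, 5000, samples, seed = 11)
  g2 <- simulateGenotypeMatrix(m, 30, 5000, samples, seed = 11)
  expect_identical(genotypes(g1), genotypes(g2))
  expect_identical(siteInfo(g1), siteInfo(g2))
  expect_true(all(genotypes(g1) %in% 0:2))
  expect_equal(sort(unique(samplePopulations(g1))),
               sort(names(samples)))
  # positions unique within each locus
  si <- siteInfo(g1)
  expect_false(any(duplicated(paste(si$chrom, si$pos))))
})

test_that("streaming ABBA accumulation equals the genotype-matrix path", {
  m <- guenonModel(phi3 = 0.004)
  samples <- c(wolfi = 1, denti = 1, mitis = 1, macaque = 1)
  gm <- simulateGenotypeMatrix(m, 150, 10000, samples, seed = 21)
  blocks <- ygeneflow:::.lociBlocks(gm, 20)
  ccR <- abbaBabaCounts(gm, "wolfi", "denti", "mitis", "macaque",
                        blocks = blocks)
  ccC <- simulateAbbaCounts(m, 150, 10000, samples, "wolfi", "denti",
                            "mitis", "macaque", nBlocks = 20, seed = 21)
  expect_equal(ccC@abba, ccR@abba)
  expect_equal(ccC@baba, ccR@baba)
  expect_equal(unname(ccC@blockAbba), unname(ccR@blockAbba))
})

test_that("monophyly frequency is exchangeable and monotone in introgression", {
  m <- ilsModel()
  expect_equal(monophylyFrequency(
    DemographicModel(c(A = 1e3, B = 1e3, AB = 1e3),
                     splits = data.frame(time = c(100, 100),
                                         derived = c("A", "B"),
                                         ancestral = "AB"),
                     ploidyMode = "y_linked"),
    "A", "B", c(A = 1, B = 1), nSims = 50, seed = 1)$frequency, 1)
  expect_error(monophylyFrequency(m, "A", "Z", c(A = 1, B = 1, C = 1)),
               "sampled")
  # denti/mitis monophyly on the Y rises with the pulse proportion
  phis <- c(0, 0.005, 0.01, 0.015, 0.02)
  freqs <- vapply(seq_along(phis), function(i) {
    y <- deriveYModel(guenonModel(phi3 = phis[i]))
    monophylyFrequency(y, "denti", "mitis",
                       c(denti = 1, wolfi = 1, mitis = 1, macaque = 1),
                       nSims = 1500, seed = 300 + i)$frequency
  }, numeric(1))
  expect_gt(cor(phis, freqs, method = "spearman"), 0)
  expect_gt(freqs[5], freqs[1])
})

test_that("PAR linkage decays with recombination and locks without it", {
  m <- guenonModel(phi3 = 0.005)
  # complete linkage: donor PAR rides the donor Y unchanged
  locked <- parLinkageProfile(m, 1e-12, nSims = 3, nYCopies = 2000,
                              maxGens = 200, nBins = 3, seed = 5)
  expect_true(all(locked$donorParAmongDonorY == 1))
  # strong recombination decays donor-PAR / donor-Y association toward the
  # population background; weaker recombination keeps more of it
  slow <- parLinkageProfile(m, 1, nSims = 12, nYCopies = 2000,
                            maxGens = 400, nBins = 3, p0 = 0.2, seed = 6)
  fast <- parLinkageProfile(m, 20, nSims = 12, nYCopies = 2000,
                            maxGens = 400, nBins = 3, p0 = 0.2, seed = 6)
  expect_true(all(fast$donorParAmongDonorY <=
                    slow$donorParAmongDonorY + 0.1))
  expect_lt(tail(fast$donorParAmongDonorY, 1),
            tail(slow$donorParAmongDonorY, 1))
  expect_error(parLinkageProfile(m, -1), "parRecMultiplier")
})
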