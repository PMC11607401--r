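test_that("ABBA/BABA counts match a brute-force per-site oracle", {
  set.seed(13)
  n <- 50
  geno <- matrix(sample(c(0L, 1L, 2L), n * 8, replace = TRUE,
                        prob = c(0.5, 0.2, 0.3)), nrow = n,
                 dimnames = list(NULL, paste0("s", 1:8)))
  # make the outgroup mostly fixed so polarization paths are exercised
  geno[, 7] <- sample(c(0L, 0L, 2L, 1L), n, replace = TRUE)
  geno[, 8] <- geno[, 7]
  pm <- setNames(rep(c("P1", "P2", "P3", "O"), each = 2),
                 paste0("s", 1:8))
  gm <- toyMatrix(geno, popMap = pm, chromLength = 1000)
  cc <- abbaBabaCounts(gm, "P1", "P2", "P3", "O", blocks = 5)
  f <- sapply(c("P1", "P2", "P3", "O"), function(p)
    rowMeans(geno[, pm == p, drop = FALSE]) / 2)
  oracle <- bruteAbba(f[, 1], f[, 2], f[, 3], f[, 4])
  expect_equal(cc@abba, unname(oracle["abba"]))
  expect_equal(cc@baba, unname(oracle["baba"]))
  expect_equal(sum(cc@blockAbba), cc@abba)
  expect_equal(sum(cc@blockBaba), cc@baba)
  # canonical single-site patterns
  one <- toyMatrix(matrix(c(0L, 2L, 2L, 0L), nrow = 1,
                          dimnames = list(NULL, paste0("s", 1:4))),
                   popMap = setNames(c("P1", "P2", "P3", "O"),
                                     paste0("s", 1:4)))
  cc1 <- abbaBabaCounts(one, "P1", "P2", "P3", "O", blocks = 1)
  expect_equal(cc1@abba, 1); expect_equal(cc1@baba, 0)
  # p1 == p2 at every site implies ABBA == BABA exactly
  geno2 <- geno; geno2[, 3:4] <- geno[, 1:2]
  gm2 <- toyMatrix(geno2, popMap = pm, chromLength = 1000)
  cc2 <- abbaBabaCounts(gm2, "P1", "P2", "P3", "O", blocks = 5)
  expect_equal(cc2@abba, cc2@baba)
  # order permutation leaves D unchanged
  perm <- sample(n)
  gmP <- toyMatrix(geno[perm, ], popMap = pm, chromLength = 1000)
  ccP <- abbaBabaCounts(gmP, "P1", "P2", "P3", "O", blocks = 1)
  expect_equal(dStatistic(ccP),
               dStatistic(abbaBabaCounts(gm, "P1", "P2", "P3", "O",
                                         blocks = 1)))
})

test_that("D statistic arithmetic and degenerate cases behave", {
  mk <- function(a, b) new("ABBACounts", abba = a, baba = b,
                           blockAbba = c(b1 = a), blockBaba = c(b1 = b),
                           nSitesUsed = 1L, nSkipped = 0L)
  expect_equal(dStatistic(mk(60, 40)), 0.2)
  expect_equal(dStatistic(mk(5, 5)), 0)
  expect_warning(d0 <- dStatistic(mk(0, 0)), "undefined")
  expect_true(is.na(d0))
})

test_that("block jackknife matches an independently coded delete-one oracle", {
  set.seed(23)
  a <- runif(20, 5, 50); b <- runif(20, 5, 50)
  cc <- new("ABBACounts", abba = sum(a), baba = sum(b),
            blockAbba = setNames(a, paste0("b", 1:20)),
            blockBaba = setNames(b, paste0("b", 1:20)),
            nSitesUsed = 100L, nSkipped = 0L)
  jk <- blockJackknifeZ(cc)
  # oracle: naive loop over deleted blocks
  dFun <- function(x, y) (x - y) / (x + y)
  dDel <- vapply(1:20, function(i)
    dFun(sum(a[-i]), sum(b[-i])), numeric(1))
  seOracle <- sqrt(19 / 20 * sum((dDel - mean(dDel))^2))
  expect_equal(jk$se, seOracle)
  expect_equal(jk$z, dFun(sum(a), sum(b)) / seOracle)
  # identical blocks: SE degenerates to zero with a warning
  ccEq <- new("ABBACounts", abba = 20, baba = 10,
              blockAbba = setNames(rep(2, 10), paste0("b", 1:10)),
              blockBaba = setNames(rep(1, 10), paste0("b", 1:10)),
              nSitesUsed = 10L, nSkipped = 0L)
  expect_warning(jkEq <- blockJackknifeZ(ccEq), "infinite")
  expect_equal(jkEq$se, 0)
  expect_true(is.infinite(jkEq$z))
  # D = 0 with positive SE gives Z = 0
  ccZ <- new("ABBACounts", abba = 10, baba = 10,
             blockAbba = setNames(c(6, 4), c("b1", "b2")),
             blockBaba = setNames(c(4, 6), c("b1", "b2")),
             nSitesUsed = 4L, nSkipped = 0L)
  expect_equal(blockJackknifeZ(ccZ)$z, 0)
  expect_error(blockJackknifeZ(new("ABBACounts", abba = 1, baba = 1,
                                   blockAbba = c(b1 = 1),
                                   blockBaba = c(b1 = 1),
                                   nSitesUsed = 1L, nSkipped = 0L)),
               "two non-empty")
  # jackknife SE shrinks roughly as 1/sqrt(blocks) on iid blocks
  set.seed(9)
  seAt <- function(nb) {
    a <- rpois(nb, 40); b <- rpois(nb, 40)
    blockJackknifeZ(new("ABBACounts", abba = sum(a), baba = sum(b),
                        blockAbba = setNames(a, seq_len(nb)),
                        blockBaba = setNames(b, seq_len(nb)),
                        nSitesUsed = 1L, nSkipped = 0L))$se
  }
  expect_gt(median(replicate(30, seAt(10))),
            median(replicate(30, seAt(160))))
})

test_that("site filters mask by allele balance and depth and drop Y hets", {
  g <- matrix(c(1L, 0L,
                2L, 1L,
                0L, 1L,
                1L, 1L,
                2L, 0L), nrow = 5, byrow = TRUE,
              dimnames = list(NULL, c("s1", "s2")))
  dp <- matrix(c(30, 30,
                 75, 30,   # s1 at 2.5x the mean: masked
                 30, 10,   # s2 at 1/3 the mean: masked
                 30, 30,
                 60, 15), nrow = 5, byrow = TRUE)  # exactly 2.0x / 0.5x kept
  mf <- matrix(c(0.20, NA,   # het below 0.25: masked
                 NA, 0.30,
                 NA, 0.40,
                 0.30, 0.25, # at threshold: kept
                 NA, NA), nrow = 5, byrow = TRUE)
  gm <- GenotypeMatrix(g, chrom = c("chr1", "chr1", "chr1", "chrY", "chr1"),
                       pos = 1:5, popMap = c(s1 = "A", s2 = "B"),
                       depth = dp, minorFrac = mf)
  out <- applySiteFilters(gm, hemizygousChroms = "chrY",
                          dropHetChroms = "chrY",
                          meanDepths = c(s1 = 30, s2 = 30))
  expect_equal(unname(out$report["hetLowBalanceMasked"]), 1L)
  expect_true(is.na(genotypes(out$matrix)[1, "s1"]))
  expect_true(is.na(genotypes(out$matrix)[2, "s1"]))  # 2.5x depth
  expect_true(is.na(genotypes(out$matrix)[3, "s2"]))  # 1/3 depth
  expect_false(any(is.na(genotypes(out$matrix)[4, ])))  # boundary retained
  # Y site het in one sample removed for all
  expect_equal(unname(out$report["yHetSitesDropped"]), 1L)
  expect_false("chrY" %in% out$matrix@chrom)
  # asking for filters without metadata names the absent fields
  gmBare <- GenotypeMatrix(g, chrom = rep("chr1", 5), pos = 1:5,
                           popMap = c(s1 = "A", s2 = "B"))
  expect_error(applySiteFilters(gmBare), "depth")
})

test_that("windowed f_d matches brute force and its boundary conventions", {
  set.seed(31)
  n <- 40
  geno <- matrix(sample(0:2, n * 4, replace = TRUE), nrow = n,
                 dimnames = list(NULL, paste0("s", 1:4)))
  geno[, 4] <- sample(c(0L, 0L, 2L), n, replace = TRUE)
  pm <- setNames(c("P1", "P2", "P3", "O"), paste0("s", 1:4))
  gm <- toyMatrix(geno, popMap = pm, posStep = 5, chromLength = 200)
  fd <- fdWindows(gm, "P1", "P2", "P3", "O", windowBp = 200)
  f <- geno / 2
  num <- den <- 0
  for (s in 1:n) {
    p <- f[s, ]
    if (p[4] > 0 && p[4] < 1) next
    if (p[4] == 1) p <- 1 - p
    pd <- max(p[2], p[3])
    num <- num + (1 - p[1]) * p[2] * p[3] - p[1] * (1 - p[2]) * p[3]
    den <- den + (1 - p[1]) * pd * pd - p[1] * (1 - pd) * pd
  }
  expected <- if (num <= 0) 0 else num / den
  expect_equal(fd$fd[1], expected)
  # P2 frequencies equal to P3 frequencies: f_d = 1 when excess is positive
  genoEq <- geno; genoEq[, 3] <- genoEq[, 2]
  genoEq[, 1] <- 0L  # make the numerator strictly positive
  gmEq <- toyMatrix(genoEq, popMap = pm, posStep = 5, chromLength = 200)
  fdEq <- fdWindows(gmEq, "P1", "P2", "P3", "O", windowBp = 200)
  expect_equal(fdEq$fd[1], 1)
})

test_that("dXY handles haploid, diploid, and missing-data denominators", {
  # two haploid samples differing at 1 of 100 comparable sites
  g <- matrix(0L, nrow = 100, ncol = 2,
              dimnames = list(NULL, c("a1", "b1")))
  g[7, 2] <- 1L
  gm <- GenotypeMatrix(g, chrom = rep("c", 100), pos = 1:100,
                       popMap = c(a1 = "A", b1 = "B"), ploidy = 1L,
                       chromLengths = c(c = 100))
  dx <- dxyWindows(gm, "A", "B", windowBp = 100, minSites = 1)
  expect_equal(dx$dxy, 0.01)
  expect_equal(dxyWindows(gm, "B", "A", windowBp = 100,
                          minSites = 1)$dxy, 0.01)  # symmetric
  # identical sequences: zero divergence
  g0 <- g; g0[7, 2] <- 0L
  gm0 <- GenotypeMatrix(g0, chrom = rep("c", 100), pos = 1:100,
                        popMap = c(a1 = "A", b1 = "B"), ploidy = 1L)
  expect_equal(dxyWindows(gm0, "A", "B", windowBp = 100,
                          minSites = 1)$dxy, 0)
  # diploid with heterozygotes and missing calls vs allele-pair brute force
  set.seed(41)
  gd <- matrix(sample(c(0:2, NA), 60 * 4, replace = TRUE,
                      prob = c(.4, .2, .3, .1)), nrow = 60,
               dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  pm <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  gmd <- toyMatrix(gd, popMap = pm, posStep = 1, chromLength = 60)
  dxd <- dxyWindows(gmd, "A", "B", windowBp = 60, minSites = 1)
  tot <- 0; nComp <- 0
  for (s in 1:60) {
    gA <- gd[s, 1:2]; gB <- gd[s, 3:4]
    if (all(is.na(gA)) || all(is.na(gB))) next
    alleles <- function(x) unlist(lapply(x[!is.na(x)], function(d)
      c(rep(1, d), rep(0, 2 - d))))
    tot <- tot + mean(outer(alleles(gA), alleles(gB), "!="))
    nComp <- nComp + 1
  }
  expect_equal(dxd$dxy, tot / nComp)
  expect_equal(dxd$nSites, nComp)
  # too few comparable sites gives a missing value
  expect_true(is.na(dxyWindows(gmd, "A", "B", windowBp = 60,
                               minSites = 1000)$dxy))
})

test_that("divergence-to-time scaling inverts exactly", {
  expect_equal(coalescenceTimeFromDxy(9.64e-4, 4.82e-9, 10), 1e6)
  expect_equal(coalescenceTimeFromDxy(0, 4.82e-9, 10), 0)
  t <- 123456
  dxy <- 2 * 4.82e-9 * (t / 10)
  expect_equal(coalescenceTimeFromDxy(dxy, 4.82e-9, 10), t)
  expect_error(coalescenceTimeFromDxy(1e-3, 0, 10), "mu")
})

test_that("jackknife block assignment covers both conventions", {
  chrom <- rep(c("c1", "c2"), each = 50)
  pos <- rep(seq(10, 500, by = 10), 2)
  perChrom <- jackknifeBlocks(chrom, pos, nBlocks = 5, perChromosome = TRUE)
  expect_equal(length(unique(perChrom)), 10)  # 5 spans x 2 chromosomes
  manyLoci <- jackknifeBlocks(rep(paste0("L", 1:100), each = 2),
                              rep(1:2, 100), nBlocks = 20)
  expect_equal(length(unique(manyLoci)), 20)
})
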