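#' Kimura diffusion fixation probability for a haploid allele
#'
#' Probability that an allele at initial frequency `p0` with haploid selective
#' advantage `s` ultimately fixes in a Wright-Fisher population of
#' `nYCopies` gene copies:
#' `(1 - exp(-2 N s p0)) / (1 - exp(-2 N s))`, with the neutral limit `p0`
#' at `s = 0`. Evaluation is overflow-safe for large `|2 N s|`.
#'
#' @param nYCopies Number of gene copies (for a Y-linked allele in a census of
#'   `N` diploids with a 1:1 sex ratio, `N / 2`).
#' @param s Selection coefficient of carriers (> -1).
#' @param p0 Initial allele frequency in `[0, 1]`.
#' @return Fixation probability (vectorized over arguments).
#' @export
#' @examples
#' kimuraFixationProbability(100000, 0.001, 0.004)  # ~0.55
#' kimuraFixationProbability(100000, 0, 0.004)      # exactly p0
kimuraFixationProbability <- function(nYCopies, s, p0) {
  .check(all(nYCopies > 0), "nYCopies must be > 0")
  .check(all(p0 >= 0 & p0 <= 1), "p0 must lie in [0, 1]")
  .check(all(s > -1), "s must be > -1")
  n <- max(length(nYCopies), length(s), length(p0))
  nYCopies <- rep_len(nYCopies, n); s <- rep_len(s, n); p0 <- rep_len(p0, n)
  a <- 2 * nYCopies * s
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] == 0) {
      out[i] <- p0[i]
    } else if (-a[i] > 700) {
      # denominator exp(-a) would overflow; P ~ exp(a (1 - p0))
      out[i] <- exp(a[i] * (1 - p0[i]))
    } else {
      out[i] <- expm1(-a[i] * p0[i]) / expm1(-a[i])
    }
  }
  out
}

.initialCopies <- function(p0, nYCopies) {
  if (p0 <= 0) return(0L)
  if (p0 >= 1) return(as.integer(nYCopies))
  max(1L, as.integer(round(p0 * nYCopies)))  # an introgressed Y is >= 1 copy
}

#' Forward Wright-Fisher trajectory of a Y-linked allele under selection
#'
#' Frequency-based haploid simulation: each generation applies deterministic
#' selection `p' = p (1 + s) / (1 + p s)` followed by binomial resampling of
#' the `nYCopies` Y chromosomes, until fixation, loss, or `maxGens`.
#'
#' @param nYCopies Number of Y copies (census diploids / 2 at a 1:1 sex
#'   ratio).
#' @param s Haploid selection coefficient of the novel Y.
#' @param p0 Initial frequency (the incoming male migration proportion); a
#'   positive `p0` starts from at least one copy.
#' @param maxGens Maximum number of generations.
#' @param seed Optional integer seed.
#' @param recordTrajectory If `TRUE`, keep the full frequency trajectory.
#' @return A list with `state` (`"fixed"`, `"lost"` or `"segregating"`),
#'   `generation` (generation of absorption, or `maxGens`), `finalFreq`, and
#'   optionally `trajectory`.
#' @export
#' @examples
#' simulateYTrajectory(1000, 0.01, 0.05, maxGens = 5000, seed = 1)$state
simulateYTrajectory <- function(nYCopies, s, p0, maxGens = 100000,
                                seed = NULL, recordTrajectory = FALSE) {
  .check(nYCopies >= 1, "nYCopies must be >= 1")
  .check(p0 >= 0 && p0 <= 1, "p0 must lie in [0, 1]")
  .check(s > -1, "s must be > -1")
  if (!is.null(seed)) set.seed(seed)
  x <- .initialCopies(p0, nYCopies)
  traj <- if (recordTrajectory) numeric(maxGens + 1) else NULL
  if (recordTrajectory) traj[1] <- x / nYCopies
  gen <- 0L
  while (gen < maxGens && x > 0 && x < nYCopies) {
    p <- x / nYCopies
    psel <- p * (1 + s) / (1 + p * s)
    x <- rbinom(1L, nYCopies, psel)
    gen <- gen + 1L
    if (recordTrajectory) traj[gen + 1] <- x / nYCopies
  }
  state <- if (x == 0) "lost" else if (x == nYCopies) "fixed" else "segregating"
  out <- list(state = state, generation = gen, finalFreq = x / nYCopies)
  if (recordTrajectory) out$trajectory <- traj[seq_len(gen + 1)]
  out
}

#' Fixation rate of a Y-linked allele over replicate forward simulations
#'
#' Runs independent replicates of the process in [simulateYTrajectory()]
#' (vectorized across replicates for speed; identical per-generation law) and
#' reports the fractions of replicates that fixed, were lost, or were still
#' segregating at `maxGens`, with a binomial confidence interval on the fixed
#' fraction.
#'
#' @inheritParams simulateYTrajectory
#' @param nReps Number of replicates (>= 1).
#' @param conf Confidence level for the interval.
#' @return A list with `fixed`, `lost`, `segregating` (fractions summing to
#'   1), `counts`, `ci` (Clopper-Pearson interval on the fixed fraction),
#'   and the parameters.
#' @export
#' @examples
#' fixationRate(1000, s = 0, p0 = 0.05, maxGens = 20000, nReps = 200,
#'              seed = 1)$fixed  # near p0
fixationRate <- function(nYCopies, s, p0, maxGens = 100000, nReps = 100,
                         seed = NULL, conf = 0.95) {
  .check(nReps >= 1, "nReps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- rep(.initialCopies(p0, nYCopies), nReps)
  absorbed <- x == 0 | x == nYCopies
  gen <- 0L
  while (gen < maxGens && !all(absorbed)) {
    idx <- which(!absorbed)
    p <- x[idx] / nYCopies
    psel <- p * (1 + s) / (1 + p * s)
    x[idx] <- rbinom(length(idx), nYCopies, psel)
    absorbed[idx] <- x[idx] == 0 | x[idx] == nYCopies
    gen <- gen + 1L
  }
  nFixed <- sum(x == nYCopies)
  nLost <- sum(x == 0)
  nSeg <- nReps - nFixed - nLost
  ci <- stats::binom.test(nFixed, nReps, conf.level = conf)$conf.int
  list(fixed = nFixed / nReps, lost = nLost / nReps,
       segregating = nSeg / nReps,
       counts = c(fixed = nFixed, lost = nLost, segregating = nSeg),
       ci = c(lower = ci[1], upper = ci[2]),
       params = list(nYCopies = nYCopies, s = s, p0 = p0,
                     maxGens = maxGens, nReps = nReps))
}

#' Two-locus forward model of Y / pseudoautosomal linkage decay
#'
#' Tracks a donor Y chromosome entering a resident population together with a
#' linked donor allele at a pseudoautosomal (PAR) locus. Each male meiosis
#' swaps the Y-borne PAR allele with a random allele from the X-borne PAR
#' pool with probability `recProb`; the association between donor-Y ancestry
#' and donor-PAR ancestry therefore decays by a factor `(1 - recProb)` per
#' generation while the overall donor-PAR frequency is conserved in
#' expectation.
#'
#' Migrant males carry the donor allele on both their Y-linked and their
#' X-linked PAR copy, so the initial overall donor-PAR frequency is `p0 / 2`
#' (the autosomal expectation under exclusively male migration at male
#' fraction `p0`).
#'
#' @param nYCopies Number of Y copies (= number of males); the X-borne PAR
#'   pool has `3 * nYCopies` copies (one per male, two per female).
#' @param p0 Initial donor-Y frequency among males.
#' @param recProb Per-generation probability that a Y-borne PAR allele
#'   recombines onto/off the X pool, in `[0, 1]`.
#' @param maxGens Number of generations to run (the simulation stops early
#'   if the donor Y is lost).
#' @param seed Optional integer seed.
#' @return data.frame with one row per generation: `gen`, `freqDonorY`,
#'   `donorParAmongDonorY`, `donorParAmongAncestralY`, `donorParOverall`, and
#'   `association` (donor-PAR frequency among donor-Y carriers minus that
#'   among ancestral-Y carriers, which decays as `(1 - recProb)^t` in
#'   expectation: both classes are pulled toward the X pool at rate
#'   `recProb` per generation).
#' @export
simulateYParLinkage <- function(nYCopies, p0, recProb, maxGens = 10000,
                                seed = NULL) {
  .check(recProb >= 0 && recProb <= 1, "recProb must lie in [0, 1]")
  .check(p0 >= 0 && p0 <= 1, "p0 must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  nY <- as.integer(nYCopies)
  nX <- 3L * nY
  nD <- .initialCopies(p0, nY)   # donor-Y males
  cD <- nD                       # donor-PAR copies riding donor Ys
  cA <- 0L                       # donor-PAR copies riding ancestral Ys
  cX <- nD                       # donor-PAR copies in the X pool (migrant X)
  out <- matrix(0, nrow = maxGens + 1, ncol = 5)
  record <- function(g) {
    qD <- if (nD > 0) cD / nD else NA_real_
    qA <- if (nD < nY) cA / (nY - nD) else NA_real_
    overall <- (cD + cA + cX) / (nY + nX)
    out[g + 1, ] <<- c(g, nD / nY, qD, qA, overall)
  }
  record(0)
  lastGen <- maxGens
  for (g in seq_len(maxGens)) {
    if (nD == 0L) { lastGen <- g - 1L; break }  # donor Y lost: stop early
    # Y drift (neutral), PAR alleles resampled within their Y class
    nD2 <- rbinom(1L, nY, nD / nY)
    cD2 <- if (nD2 > 0 && nD > 0) rbinom(1L, nD2, cD / nD) else 0L
    cA2 <- if (nD2 < nY && nD < nY) rbinom(1L, nY - nD2, cA / (nY - nD)) else 0L
    cX2 <- rbinom(1L, nX, cX / nX)
    # recombination: swaps between Y-borne and X-borne PAR copies
    if (recProb > 0) {
      qX <- cX2 / nX
      rD <- rbinom(1L, nD2, recProb)
      rA <- rbinom(1L, nY - nD2, recProb)
      lossD <- if (nD2 > 0) rbinom(1L, rD, cD2 / nD2) else 0L
      lossA <- if (nD2 < nY) rbinom(1L, rA, cA2 / (nY - nD2)) else 0L
      gainD <- rbinom(1L, rD, qX)
      gainA <- rbinom(1L, rA, qX)
      cD2 <- cD2 - lossD + gainD
      cA2 <- cA2 - lossA + gainA
      cX2 <- max(0L, min(nX, cX2 + lossD + lossA - gainD - gainA))
    }
    nD <- nD2; cD <- max(0L, min(cD2, nD)); cA <- max(0L, min(cA2, nY - nD))
    cX <- cX2
    record(g)
  }
  out <- as.data.frame(out[seq_len(lastGen + 1), , drop = FALSE])
  names(out) <- c("gen", "freqDonorY", "donorParAmongDonorY",
                  "donorParAmongAncestralY", "donorParOverall")
  out$association <- out$donorParAmongDonorY - out$donorParAmongAncestralY
  out
}
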