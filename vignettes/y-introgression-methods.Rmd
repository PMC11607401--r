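---
title: "Simulating and detecting Y chromosome introgression between divergent primate lineages"
author: "ygeneflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting Y chromosome introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ygeneflow)
```

## The problem

Under Haldane's rule, hybrid fitness loss concentrates in the heterogametic
sex, so the mammalian Y chromosome rarely crosses species boundaries, and
essentially never between deeply divergent lineages. The guenon
*Cercopithecus denti* is a striking exception: its autosomes place it firmly
in the *mona* group, but its Y chromosome is nested inside the *mitis*
group, sister to *C. mitis opisthostictus* — lineages that had already been
separated for millions of years when the transfer happened. Demonstrating
that this Y both introgressed and then *fixed* in the recipient requires a
chain of population-genomic machinery: a demographic model with
introgression pulses; coalescent simulation under that model; the
ABBA-BABA D-statistic with a block-jackknife significance test; windowed
f_d and dXY; forward Wright-Fisher simulation of a Y-linked allele under
selection; coverage-based detection of the pseudoautosomal region (PAR) and
of candidate copy-number expansions; a sliding-window tree scan; and a
screen of Y-linked genes for clade-fixed amino-acid changes. `ygeneflow`
implements that chain end to end, with synthetic-data generators so every
stage can be exercised and scored against planted truth without any
sequencing data.

## The demographic model

`DemographicModel` holds populations (with piecewise-constant diploid Ne),
divergence events ("splits", backward in time), and instantaneous
unidirectional introgression pulses: at pulse time `t`, each lineage in the
destination relocates to the source with probability `phi` (forward in
time, a fraction `phi` of the destination descends from source migrants).
Pulses are single-generation events rather than continuous migration bands,
matching the multispecies-coalescent-with-introgression (MSci) convention.
Time is counted backward from the present in generations; years are only a
reporting conversion, `generationsToYears()`.

`guenonModel()` encodes the nine-taxon default: the eastern *mona* clade
(*denti*, *wolfi*, *pogonias*) plus *mona*, *neglectus*, the *cephus*
lineage, the *mitis* group (*nictitans*, *mitis* = *C. m. opisthostictus*),
and the rhesus macaque outgroup. Three pulses are calibrated quantities:
2.1% from the *mitis*-group ancestor into the *denti*/*wolfi*/*pogonias*
ancestor at 310,000 generations ago, 8.5% from the *cephus* lineage into
the same recipient at 270,000 generations ago, and a configurable pulse
(`phi3`, the experimental knob) from *mitis* into *denti* at 100,000
generations ago — 10,000 generations after the *denti*/*wolfi* split at
110,000 generations ago. The mutation rate is 4.82e-9 per bp per
generation and the generation time 10 years, so the *mitis*/*mona*
divergence at 800,000 generations corresponds to ~8 Mya.

Two classes of parameter deserve comment because they are package choices,
not published numbers:

* **Branch Ne.** Published support gives branch-specific Ne only
  graphically, with the text stating sizes are generally large (>100,000)
  and using 200,000 for forward simulation. Every branch therefore
  defaults to Ne = 200,000 diploids, overridable per population.
* **Uncalibrated split times.** The macaque root (1,350,000 generations),
  the *mona*-group joins (*pogonias* at 200,000, *mona* at 450,000), the
  *mitis*-group crown (250,000) and the deeper joins (550,000 / 650,000 /
  800,000) are defaults chosen to be consistent with the ~8 My
  *mitis*/*mona* divergence and constrained so that each pulse references
  populations alive at its time: the recipient ancestor must already exist
  at 270,000-310,000 generations (hence *pogonias* joins more recently
  than 270,000 and *mona* earlier than 310,000), and the *mitis*-group
  ancestral branch must span 310,000 generations.

`deriveYModel()` converts an autosomal model to its Y-linked counterpart:
every Ne is divided by four (Ne_Y / Ne_autosomes = 0.25) and every pulse
proportion doubled (capped at 1), the conservative expectation under
exclusively male-mediated migration. `harmonicMeanNe()` collapses Ne
epochs along a branch path the way MSci output is summarized.

## The coalescent simulator

`simulateGeneTree()` runs a structured coalescent backward in time: within
a population of (ploidy-scaled) size Ne each lineage pair coalesces at
exponential rate 1/(2 Ne) per generation; pulse, split, and Ne-epoch
boundaries are handled by exact event scheduling, with continuous
exponential waiting times in between (no generation-by-generation
stepping). A diploid sample contributes two lineages in autosomal mode and
one in `y_linked` mode. The engine is compiled (Rcpp) and uses R's RNG, so
a single `set.seed()` governs reproducibility; all drivers expand one
master seed into per-replicate streams with `deriveSeed()`, a
multiplicative hash that keeps every derived seed below 2^31 and makes
replicates order-independent.

Mutations are overlaid under the infinite-sites model
(`overlayMutations()`): Poisson(branch length x mu x locus length)
mutations per branch, each a new biallelic site carried by exactly the
leaves below it. There is no intra-locus recombination: the 1-Mb
recombining loci of the original experimental design are represented as
independent non-recombining loci, with the locus count as the knob that
controls the variance of downstream statistics (see the calibration note
below). `simulateGenotypeMatrix()` assembles per-locus site patterns into
a `GenotypeMatrix` (diploid dosages by pairing each sample's two
lineages), each locus its own chromosome with distinct uniform site
positions. `simulateAbbaCounts()` is a streaming equivalent that
accumulates frequency-weighted ABBA/BABA sums inside the engine — under
the same seed it is exactly identical to the two-step path (this is
property-tested), and it lets the migration grid use very large locus
counts in constant memory.

`monophylyFrequency()` reports how often two taxa form an exclusive clade,
the quantity used to ask how often *denti* and *mitis* would be sisters on
the Y under drift alone; its closed-form anchors (frequency 1 for two
taxa, the (1/3)e^(-T/(2Ne)) incomplete-lineage-sorting rate for a three-taxon
asymmetric tree) are the simulator's oracle tests.

## Forward Wright-Fisher simulation of Y fixation

The individual-based forward model of the original design reduces, for a
single Y-linked locus, to a haploid Wright-Fisher process on
`nYCopies = N/2` chromosomes (1:1 sex ratio): deterministic selection
`p' = p (1 + s) / (1 + p s)` followed by binomial resampling
(`simulateYTrajectory()`, vectorized across replicates in
`fixationRate()`). The two processes share the same diffusion limit, and
the Kimura fixation probability

$$P_{fix} = \frac{1 - e^{-2 N s p_0}}{1 - e^{-2 N s}}$$

(`kimuraFixationProbability()`, overflow-safe, with the neutral limit
`p0`) is used as the independent oracle: across a grid of s and p0 the
simulated fixation fractions must sit within three binomial standard
errors of the diffusion value. A positive initial frequency always starts
from at least one copy — an introgressed Y exists physically.
"Segregating at the horizon" is reported as its own outcome state, never
folded into fixed or lost: at N_Y = 100,000 the conditional neutral
fixation time far exceeds a 100,000-generation horizon, which is exactly
why drift alone essentially never fixes the introgressed Y within the
simulated window.

The two-locus model `simulateYParLinkage()` tracks a donor Y together
with a linked PAR allele: each male meiosis swaps the Y-borne PAR allele
with a random allele from the X-borne pool (3 nYCopies copies: one per
male, two per female) with probability `recProb`. The donor-PAR excess
among donor-Y carriers relative to ancestral-Y carriers decays as
(1 - recProb)^t in expectation — the closed-form oracle — while the
overall donor-PAR frequency is a martingale. `parLinkageProfile()` maps
this along a 150-kb PAR with per-bin recombination
`multiplier x 4.48e-9 x distance`, averaging replicate runs (single runs
are bistable once the donor-Y PAR pool coalesces) and discarding runs that
lose the donor Y, as the original design did. At a tenfold recombination
multiplier the distal PAR decouples from the Y within a few thousand
generations and its donor-ancestry fraction approaches the autosomal
expectation.

## Site statistics

* **Filters** (`applySiteFilters()`): heterozygous calls with minor-allele
  read fraction below 0.25 become missing; per-sample calls outside
  [0.5x, 2x] of the sample's relevant mean depth (genome-wide, or
  chromosome-wide on the sex chromosomes) become missing, boundaries
  retained; Y sites heterozygous in any sample are dropped entirely. The
  reference means can be supplied explicitly, since the matrix at hand is
  often a slice of the genome they were estimated from.
* **D** (`abbaBabaCounts()`, `dStatistic()`): frequency-weighted
  (population-level) ABBA/BABA, per site
  `(1-p1) p2 p3 (1-pO)` and `p1 (1-p2) p3 (1-pO)` after polarizing on a
  fixed outgroup allele; sites with a polymorphic or missing outgroup are
  skipped. D = (ABBA - BABA)/(ABBA + BABA); a zero denominator is
  undefined (NA), not zero.
* **Jackknife** (`blockJackknifeZ()`): delete-one-block pseudovalues,
  `SE = sqrt((n-1)/n * sum((D_-i - mean)^2))`, significance Z > 3
  one-sided in the direction of excess P2-P3 sharing.
  `jackknifeBlocks()` supports both conventions used in practice: 20
  equal-length spans per chromosome for real multi-chromosome data, and
  20 contiguous groups of whole loci for simulated datasets.
* **f_d** (`fdWindows()`): the windowed admixture-fraction estimator with
  the per-site donor `P_D = argmax(p2, p3)`; windows with non-positive
  numerator report 0, zero denominators are missing.
* **dXY** (`dxyWindows()`): mean per-site cross-population allele
  differences over comparable sites, including invariant ones, so missing
  data shrink the denominator and never inflate divergence. Synthetic
  VCFs carry explicit invariant records; large in-memory simulated
  matrices may instead declare complete coverage, in which case the
  denominator is the window width. A 50-kb window needs at least 100
  comparable sites (configurable) to report a value.
  `coalescenceTimeFromDxy()` scales divergence to time as
  `t = (dXY / (2 mu)) * g`.

## Coverage scans

`normalizeCoverage()` divides window depths by the autosomal mean (PAR
detection) or the chromosome-wide mean (CNV scan), recording the divisor.
`detectPar()` segments the male X into a diploid-like and a haploid-like
state. Rather than merging thresholded run-lengths — which a handful of
noisy windows at a chromosome end can derail — it places a least-squares
single changepoint, classifies the two segment means against the 0.75
decision boundary, requires each segment to span at least `minRun`
windows with three quarters of its windows on its own side of the
boundary, and calls the terminal diploid-like segment anchored at a
chromosome end as the PAR. A female track, when given, must be
autosome-like across the call. With 10-kb windows and Poisson depth noise
at mean 30 the boundary is recovered exactly in most replicates and within
two windows on average; rare noise clusters directly at the boundary can
legitimately displace the estimate, a limit of the data rather than of the
estimator.

`cnvRatioScan()` forms per-window target/reference coverage ratios (both
tracks chromosome-mean normalized, identical 5-kb/1-kb sliding windows;
zero-depth reference windows are skipped), keeps windows at ratio >=
`minRatio` against every reference, merges windows whose spans overlap,
and reports merged regions that contain at least `minSpanWindows`
qualifying windows (default 10, i.e. a >= 10 kb signal) *and* average at
least `minRatio` across their whole span — the span-mean condition keeps
isolated noise excursions from promoting sub-threshold regions. One known
artifact is inherent to chromosome-mean normalization: a large expansion
inflates the target's chromosome mean and so depresses its background
ratio; the planted-truth tests cover this regime.

## Window trees and the coding screen

`windowDistanceMatrix()` computes expected allele mismatch per comparable
site between samples (`p_i(1-p_j) + p_j(1-p_i)` with `p = dosage/ploidy`),
optionally Jukes-Cantor corrected (saturation at p >= 0.75 is an error).
`neighborJoining()` is canonical Saitou-Nei NJ with a pinned tie-break
(lowest current-index pair) and negative branch lengths clamped to zero
with the deficit transferred to the sister branch, so outputs are
deterministic; on additive matrices it is exact, which random additive
trees property-test against the field-standard implementation.
`classifyWindowTopology()` roots on the outgroup and labels a window
`y_like` only when all three clade conditions hold: the focal taxon is
nested in a monophyletic donor-group clade, sister to the donor species,
and its own group excluding it is monophyletic. `scanGenomeTopology()`
applies this in non-overlapping 10-kb windows, treating windows with more
than 50% missing data or fewer than 20 variable sites as unresolved
(defaults chosen to keep spurious clades out of sparse windows), and
merges adjacent `y_like` windows into regions.

`translateCds()` / `fixedAaDifferences()` / `codingScreen()` screen
per-gene CDS alignments: standard genetic code without initiator-codon
special-casing, gaps and ambiguities to X; genes with an internal stop in
any focal sample are excluded entirely; a position counts as a fixed
difference only when each clade is internally fixed (X and gaps are not
calls; one non-missing call per clade suffices — the missing-data policy
is a package decision) and the residues differ.

## Synthetic data and what it does (not) emulate

`generateStudyGenotypes()` writes VCF (with explicit invariant records),
population map, and a JSON truth file for the nine-taxon design;
`generateCoverageTracks()` plants a 2.36-Mb PAR at the start of an X-like
chromosome and fold-change regions (default one 1.35-Mb 4x expansion) on
a Y-like chromosome under Poisson window noise (negative-binomial
overdispersion available); `generateCdsFixtures()` plants clade-fixed
amino-acid differences (default scale: 13 genes with at least one
difference, the top gene with five, plus stop-codon exclusions). All
generators are byte-deterministic given a seed, and every planted truth is
emitted machine-readably, so downstream modules are scored without
reference to generator internals.

What the generators deliberately do not emulate: linkage and recombination
within loci (loci are exchangeable independent genealogies), mapping bias
and repeat masking, read-level errors (coverage is window-level noise, not
reads), spatial autocorrelation of coverage, and transcript-model
ambiguity (one CDS per gene is the contract). Passing tests therefore
certify the statistical machinery against its models and planted truth,
not robustness to alignment artifacts in real sequencing data.

## Experiment drivers and problem sizes

`runFig6bExperiment()` tabulates fixed/lost/segregating fractions over a
selection x initial-frequency grid (defaults: s in {0, 0.001, 0.01}, six
frequencies 0.1-1%, 100 replicates of 100,000 generations at 100,000 Y
copies) next to the diffusion prediction.

`runFig6aExperiment()` runs the migration grid (0-1% in 0.05% steps, 10
replicates per rate), computing frequency-weighted D and the 20-block
jackknife Z per replicate and reporting the smallest rate at which every
replicate is significant (with a stricter from-here-upward variant as a
secondary summary: that variant is inflated whenever a single replicate at
any higher rate narrowly misses Z = 3, so the first-10-of-10 rate is the
headline number). One sizing decision matters here. The
original design simulated 100 Mb as 100 recombining 1-Mb loci; ancestral
recombination decorrelates genealogies at scales far below 1 Mb, so that
design carries many more effectively independent genealogies than 100. A
like-for-like stand-in with independent 10-kb loci must match that
*precision*, not that base-pair count: at 5,000 or even 10,000 independent
loci the jackknife SE of D (~0.022-0.032) exceeds the expected D response
at a 0.4% pulse (~0.028), and no rate on the grid could ever be
consistently significant. The default of 155,000 loci per replicate sets
the jackknife SE near 0.006, the level at which the demography's own D
response makes "consistently significant above 0.4%" a coherent statement
(expected Z ~ 4.7 at 0.4%, ~ 4 at 0.35%). This is a one-time calibration
against the measured D response and variance curves, stated here as the
package's definition of the scaled-down experiment.

`runGenomeScans()` consolidates D/f_d/dXY tables, the topology scan, the
PAR/CNV coverage scans, and the coding screen over one dataset, writing
TSV/BED outputs and a markdown summary with per-stage row counts; any
stage failure halts with the stage named.

Test-suite problem sizes are scaled to keep the full suite fast while
leaving the statistical assertions meaningful: closed-form oracles run at
2,000-6,000 replicates, the diffusion-oracle grids at 400-1,000
replicates, and the small migration-grid smoke test at 6,000 loci with the
trend assertion widened to tolerate one adjacent rank swap at that size.
The full-scale grid and the 100-replicate fixation cells are exercised in
the acceptance suite and by `scripts/acceptance.R`.

## Known limitations

* Instantaneous pulses only; continuous migration is out of scope.
* No ancestral recombination graph: intra-locus linkage is absent, and the
  locus count is an explicit variance calibration, not a genome length.
* The forward model is frequency-based Wright-Fisher; departures from WF
  offspring variance (harem structure, sweepstakes reproduction) would
  rescale effective sizes.
* Selection against hybrid backgrounds (the mechanism behind Haldane's
  rule) is not modeled, which makes the selection coefficients required
  for fixation conservative.
* The PAR caller assumes a single terminal PAR per chromosome; two-ended
  calls are made one end at a time.
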