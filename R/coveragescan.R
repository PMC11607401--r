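# Coverage-based detection of the pseudoautosomal region (male half-coverage
# plateau) and of copy-number-expanded regions (cross-sample ratio scan).
# A coverage track is a data.frame with columns sample, chrom, start, end
# (0-based half-open windows of fixed width) and depth.

.checkTrack <- function(track) {
  .check(all(c("sample", "chrom", "start", "end", "depth") %in% names(track)),
         "a coverage track needs sample/chrom/start/end/depth columns")
  .check(all(track$depth >= 0, na.rm = TRUE), "depths must be >= 0")
  invisible(track)
}

#' Normalize a coverage track
#'
#' Divides each window's depth by the autosomal mean (for PAR detection) or
#' by the chromosome-wide mean (for the CNV scan). The divisor(s) and mode
#' are recorded as attributes, so multiplying back recovers the input.
#'
#' @param track Coverage track data.frame (sample, chrom, start, end,
#'   depth).
#' @param mode `"autosomal_mean"` or `"chromosome_mean"`.
#' @param autosomes Chromosome names considered autosomal (default: all
#'   chromosomes not named `chrX`/`chrY`/`X`/`Y`).
#' @return The track with normalized `depth` and attributes
#'   `normalization` (mode) and `divisor` (named numeric).
#' @export
normalizeCoverage <- function(track,
                              mode = c("autosomal_mean", "chromosome_mean"),
                              autosomes = NULL) {
  mode <- match.arg(mode)
  .checkTrack(track)
  if (mode == "autosomal_mean") {
    if (is.null(autosomes))
      autosomes <- setdiff(unique(track$chrom), c("chrX", "chrY", "X", "Y"))
    div <- mean(track$depth[track$chrom %in% autosomes], na.rm = TRUE)
    .check(is.finite(div) && div > 0, "autosomal mean depth is zero")
    track$depth <- track$depth / div
    divisor <- c(autosomal = div)
  } else {
    means <- tapply(track$depth, track$chrom, mean, na.rm = TRUE)
    divisor <- setNames(as.numeric(means), names(means))
    .check(all(divisor > 0), "a chromosome has zero mean depth")
    track$depth <- track$depth / divisor[track$chrom]
  }
  attr(track, "normalization") <- mode
  attr(track, "divisor") <- divisor
  track
}

# least-squares single changepoint: the split minimizing within-segment
# sum of squares (equivalently maximizing the between-segment contrast)
.bestChangepoint <- function(d) {
  n <- length(d)
  cs <- cumsum(d); cs2 <- cumsum(d^2)
  c1 <- seq_len(n - 1)
  sseL <- cs2[c1] - cs[c1]^2 / c1
  sseR <- (cs2[n] - cs2[c1]) - (cs[n] - cs[c1])^2 / (n - c1)
  which.min(sseL + sseR)
}

#' Detect the pseudoautosomal region from male X-chromosome coverage
#'
#' On the non-recombining X a male maps at half the autosomal depth; in the
#' PAR, at full depth. The male track (normalized by the autosomal mean) is
#' segmented into a near-1.0 and a near-0.5 state by a least-squares single
#' changepoint; the two segment means are classified against the decision
#' boundary `boundary`, each segment must span at least `minRun` windows
#' and be internally consistent (at least three quarters of its windows on
#' its own side of the boundary), and the PAR call is the terminal
#' near-1.0 segment anchored at a chromosome end. A female track, when
#' given, is checked for near-1.0 coverage across the call.
#'
#' @param maleTrack Normalized male X coverage (one chromosome, >= 50
#'   windows, ordered by position).
#' @param femaleTrack Optional normalized female track over the same
#'   windows.
#' @param boundary Decision boundary between the diploid-like and
#'   haploid-like states.
#' @param minRun Minimum run length (windows) for a state segment.
#' @return A list with `par` (data.frame chrom/start/end; zero rows when no
#'   PAR) and `flags` (character vector; may include
#'   `"no non-PAR detected"`, `"no PAR detected"`,
#'   `"female coverage inconsistent"`).
#' @export
detectPar <- function(maleTrack, femaleTrack = NULL, boundary = 0.75,
                      minRun = 5) {
  .checkTrack(maleTrack)
  .check(length(unique(maleTrack$chrom)) == 1,
         "detectPar expects a single chromosome")
  .check(nrow(maleTrack) >= 50, "need at least 50 windows")
  maleTrack <- maleTrack[order(maleTrack$start), ]
  d <- maleTrack$depth
  n <- length(d)
  flags <- character()
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  hiFrac <- function(win) mean(d[win] >= boundary)
  if (mean(d) >= boundary && hiFrac(seq_len(n)) >= 0.75)
    return(list(par = empty, flags = "no non-PAR detected"))
  cp <- .bestChangepoint(d)
  left <- seq_len(cp); right <- (cp + 1):n
  mL <- mean(d[left]); mR <- mean(d[right])
  segOk <- function(win, hi) {
    length(win) >= minRun &&
      (if (hi) hiFrac(win) >= 0.75 else hiFrac(win) <= 0.25)
  }
  win <- NULL
  if (mL >= boundary && mR < boundary &&
      segOk(left, TRUE) && segOk(right, FALSE)) {
    win <- left                     # PAR anchored at the chromosome start
  } else if (mR >= boundary && mL < boundary &&
             segOk(right, TRUE) && segOk(left, FALSE)) {
    win <- right                    # PAR anchored at the chromosome end
  }
  if (is.null(win))
    return(list(par = empty, flags = "no PAR detected"))
  par <- data.frame(chrom = maleTrack$chrom[1],
                    start = min(maleTrack$start[win]),
                    end = max(maleTrack$end[win]))
  if (!is.null(femaleTrack)) {
    .checkTrack(femaleTrack)
    f <- femaleTrack[femaleTrack$chrom == par$chrom &
                       femaleTrack$start >= par$start &
                       femaleTrack$end <= par$end, ]
    if (nrow(f) && mean(f$depth, na.rm = TRUE) < boundary)
      flags <- c(flags, "female coverage inconsistent")
  }
  list(par = par, flags = flags)
}

#' Scan for copy-number-expanded regions by coverage ratio
#'
#' Computes the per-window coverage ratio of a target sample against one or
#' more reference samples (all tracks normalized to the chromosome-wide
#' mean, with identical windowing) and merges runs of at least
#' `minSpanWindows` consecutive windows whose ratio is at least `minRatio`
#' against every reference. Overlapping (sliding) windows are merged on
#' genomic span. Reference windows with zero depth are skipped.
#'
#' @param target Normalized target track.
#' @param references A normalized reference track, or list of them.
#' @param minRatio Minimum target/reference ratio to call (default 2); the
#'   merged span must also average at least this ratio.
#' @param minSpanWindows Minimum number of qualifying windows in a merged
#'   region (default 10, i.e. a >= 10 kb signal under the 5 kb / 1 kb
#'   sliding-window geometry).
#' @return data.frame of regions (chrom, start, end, nWindows, meanRatio);
#'   zero rows when nothing is called.
#' @export
cnvRatioScan <- function(target, references, minRatio = 2.0,
                         minSpanWindows = 10) {
  .checkTrack(target)
  if (is.data.frame(references)) references <- list(references)
  target <- target[order(target$chrom, target$start), ]
  key <- function(t) paste(t$chrom, t$start, t$end)
  ratios <- sapply(references, function(ref) {
    .checkTrack(ref)
    .check(identical(key(target), key(ref[order(ref$chrom, ref$start), ])),
           "target and reference tracks must share the same windows")
    ref <- ref[order(ref$chrom, ref$start), ]
    r <- target$depth / ref$depth
    r[!is.finite(r) | ref$depth == 0] <- NA  # zero-depth reference: skip
    r
  })
  if (is.null(dim(ratios))) ratios <- matrix(ratios, ncol = length(references))
  pass <- rowSums(ratios >= minRatio, na.rm = TRUE) == ncol(ratios) &
    rowSums(is.na(ratios)) == 0
  meanRatio <- rowMeans(ratios)
  out <- list()
  for (ch in unique(target$chrom)) {
    i <- which(target$chrom == ch & pass)
    if (!length(i)) next
    # merge passing windows whose genomic spans overlap or touch (sliding
    # windows overlap heavily, so this both joins runs and bridges single
    # noisy dropouts covered by neighbouring windows)
    o <- i[order(target$start[i])]
    cluster <- cumsum(c(1, target$start[o][-1] > cummax(
      target$end[o][-length(o)])))
    chAll <- which(target$chrom == ch)
    for (cl in split(o, cluster)) {
      if (length(cl) < minSpanWindows) next
      s0 <- min(target$start[cl]); e0 <- max(target$end[cl])
      # judge the merged span by its overall mean ratio (all windows in the
      # span, passing or not), so isolated noise excursions cannot promote
      # a sub-threshold region
      span <- chAll[target$start[chAll] >= s0 & target$end[chAll] <= e0]
      spanMean <- mean(meanRatio[span], na.rm = TRUE)
      if (!is.finite(spanMean) || spanMean < minRatio) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = s0, end = e0, nWindows = length(cl),
        meanRatio = spanMean)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), nWindows = integer(),
                      meanRatio = numeric()))
  do.call(rbind, out)
}
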