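#' @useDynLib ygeneflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rpois rbinom setNames qnorm sd cor complete.cases
#' @importFrom utils write.table read.table head tail
NULL

#' Derive a reproducible child seed from a master seed
#'
#' Expands one user-supplied seed into independent per-stage / per-replicate
#' seeds with a multiplicative hash, so replicates are reproducible and
#' order-independent. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed Master seed (single integer).
#' @param ... One or more integer indices identifying the stream
#'   (e.g. stage number, replicate number).
#' @return A single integer seed.
#' @export
#' @examples
#' deriveSeed(1, 3, 7)
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    # Lehmer-style mixing; all arithmetic exact in doubles (< 2^53)
    h <- (h * 48271 + as.double(k) * 16807 + 11) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# internal: stop with a validation-flavoured message
.check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# internal: non-overlapping 0-based half-open windows covering [0, len)
.makeWindows <- function(len, width) {
  starts <- seq(0, max(len - 1, 0), by = width)
  data.frame(start = starts, end = pmin(starts + width, len))
}

#' Write a BED file of 0-based half-open intervals
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (plus any
#'   extra columns, written as additional BED fields).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBed <- function(regions, path) {
  .check(all(c("chrom", "start", "end") %in% names(regions)),
         "regions must have chrom/start/end columns")
  ord <- c("chrom", "start", "end",
           setdiff(names(regions), c("chrom", "start", "end")))
  write.table(regions[, ord, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
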