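#' GenotypeMatrix: sites-by-samples derived-allele dosages
#'
#' An S4 container for biallelic genotype dosages with genomic coordinates,
#' a sample-to-population map, and optional per-call depth and minor-allele
#' read-fraction metadata used by the site filters. Dosages are derived
#' (non-reference) allele counts: `0/1/2` for diploids, `0/1` for haploid
#' (Y-linked) data, `NA` for missing. Invariant sites (dosage 0 everywhere)
#' are retained so that dXY denominators can count all comparable sites.
#'
#' @slot geno Integer matrix, sites x samples; column names are sample ids.
#' @slot chrom Character vector of chromosome / locus ids per site.
#' @slot pos Integer vector of 1-based positions per site (VCF convention;
#'   window functions convert to 0-based half-open internally).
#' @slot ploidy 1 (haploid / Y) or 2 (diploid).
#' @slot popMap Named character: sample id -> population.
#' @slot chromLengths Named numeric vector of chromosome lengths (may be
#'   empty; required by `completeCoverage` dXY denominators).
#' @slot depth Optional numeric matrix of per-call read depths (or NULL).
#' @slot minorFrac Optional numeric matrix of minor-allele read fractions for
#'   heterozygous calls (or NULL).
#' @export
setClass("GenotypeMatrix",
  representation(
    geno = "matrix", chrom = "character", pos = "integer",
    ploidy = "integer", popMap = "character",
    chromLengths = "numeric", depth = "ANY", minorFrac = "ANY"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  g <- object@geno
  if (length(object@chrom) != nrow(g) || length(object@pos) != nrow(g))
    msgs <- c(msgs, "chrom/pos must have one entry per site (row)")
  if (is.null(colnames(g)) || anyDuplicated(colnames(g)))
    msgs <- c(msgs, "geno must have unique sample column names")
  if (!object@ploidy %in% c(1L, 2L))
    msgs <- c(msgs, "ploidy must be 1 or 2")
  if (length(g) && !all(is.na(g))) {
    rng <- range(g, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > object@ploidy)
      msgs <- c(msgs, "dosages must lie in [0, ploidy]")
  }
  if (!all(colnames(g) %in% names(object@popMap)))
    msgs <- c(msgs, "popMap must cover every sample")
  for (m in c("depth", "minorFrac")) {
    x <- slot(object, m)
    if (!is.null(x) && !identical(dim(x), dim(g)))
      msgs <- c(msgs, sprintf("%s must match geno dimensions", m))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param geno Integer matrix of dosages (sites x samples), with sample ids
#'   as column names.
#' @param chrom,pos Site coordinates (1-based positions).
#' @param popMap Named character vector: sample -> population.
#' @param ploidy 1 or 2.
#' @param chromLengths Optional named numeric vector of chromosome lengths.
#' @param depth,minorFrac Optional metadata matrices matching `geno`.
#' @return A validated [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(geno, chrom, pos, popMap, ploidy = 2L,
                           chromLengths = NULL, depth = NULL,
                           minorFrac = NULL) {
  storage.mode(geno) <- "integer"
  obj <- new("GenotypeMatrix", geno = geno, chrom = as.character(chrom),
             pos = as.integer(pos), ploidy = as.integer(ploidy),
             popMap = popMap,
             chromLengths = if (is.null(chromLengths)) numeric() else chromLengths,
             depth = depth, minorFrac = minorFrac)
  validObject(obj)
  obj
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d sites x %d samples (%s)\n",
              nrow(object@geno), ncol(object@geno),
              if (object@ploidy == 1) "haploid" else "diploid"))
  cat(sprintf("  chromosomes: %d; populations: %s\n",
              length(unique(object@chrom)),
              paste(unique(object@popMap[colnames(object@geno)]),
                    collapse = ", ")))
  invisible(object)
})

#' @describeIn GenotypeMatrix-class dosage matrix accessor
#' @param x,object A GenotypeMatrix.
#' @export
genotypes <- function(x) x@geno

#' @describeIn GenotypeMatrix-class site coordinates as a data.frame
#' @export
siteInfo <- function(x) data.frame(chrom = x@chrom, pos = x@pos)

#' @describeIn GenotypeMatrix-class sample -> population map
#' @export
samplePopulations <- function(x) x@popMap[colnames(x@geno)]

#' @describeIn GenotypeMatrix-class number of sites
#' @export
nSites <- function(x) nrow(x@geno)

#' Subset a GenotypeMatrix by sites and/or samples
#' @param x A [GenotypeMatrix-class].
#' @param i Site (row) index.
#' @param j Sample (column) index or names.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  new("GenotypeMatrix", geno = x@geno[i, j, drop = FALSE],
      chrom = x@chrom[i], pos = x@pos[i], ploidy = x@ploidy,
      popMap = x@popMap, chromLengths = x@chromLengths,
      depth = sub(x@depth), minorFrac = sub(x@minorFrac))
})

# internal: derived-allele frequency per site for one population
.popFreq <- function(gm, pop) {
  samples <- names(gm@popMap)[gm@popMap == pop]
  samples <- intersect(samples, colnames(gm@geno))
  .check(length(samples) > 0, sprintf("no samples for population '%s'", pop))
  g <- gm@geno[, samples, drop = FALSE]
  rowMeans(g, na.rm = TRUE) / gm@ploidy  # NaN when all missing
}

# internal: derived-allele count and called-allele count per site for a pop
.popCounts <- function(gm, pop) {
  samples <- names(gm@popMap)[gm@popMap == pop]
  samples <- intersect(samples, colnames(gm@geno))
  .check(length(samples) > 0, sprintf("no samples for population '%s'", pop))
  g <- gm@geno[, samples, drop = FALSE]
  list(derived = rowSums(g, na.rm = TRUE),
       called = gm@ploidy * rowSums(!is.na(g)))
}

#' Read a (possibly invariant-site) VCF into a GenotypeMatrix
#'
#' Biallelic SNV and invariant records are kept; indels and multi-allelic
#' records are dropped. Per-call `DP` and the minor-allele read fraction from
#' `AD` are carried along when present in the FORMAT fields.
#'
#' @param path VCF file (plain text or gzipped).
#' @param popMap Named character vector sample -> population, or path to a
#'   two-column TSV (sample, population).
#' @param ploidy 1 or 2; haploid input may be encoded as diploid homozygous
#'   calls in the VCF.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeVcf <- function(path, popMap, ploidy = 2L) {
  if (is.character(popMap) && length(popMap) == 1 && file.exists(popMap)) {
    pm <- read.table(popMap, header = FALSE, sep = "\t",
                     col.names = c("sample", "population"),
                     stringsAsFactors = FALSE)
    popMap <- setNames(pm$population, pm$sample)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1 & (is.na(alt) | alt == "." |
                             (nchar(alt) == 1 & !grepl(",", alt)))
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  nAlt <- function(x) {
    # count '1' alleles; any missing allele -> NA
    out <- rep(NA_integer_, length(x))
    known <- !is.na(x) & !grepl("\\.", x)
    out[known] <- vapply(strsplit(gsub("\\|", "/", x[known]), "/"),
                         function(a) sum(a == "1"), integer(1))
    out
  }
  geno <- apply(gt, 2, nAlt)
  if (is.null(dim(geno)))
    geno <- matrix(geno, nrow = sum(keep), dimnames = list(NULL, colnames(gt)))
  if (ploidy == 1L) geno <- pmin(geno, 1L)  # haploid-as-homozygous encoding
  storage.mode(geno) <- "integer"
  fmt <- character()
  if (nrow(v@gt)) fmt <- unlist(strsplit(v@gt[1, "FORMAT"], ":"))
  depth <- NULL
  if ("DP" %in% fmt) {
    depth <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, ,
                                                                    drop = FALSE]
  }
  minorFrac <- NULL
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
    minorFrac <- apply(ad, 2, function(x) {
      vapply(strsplit(x, ","), function(a) {
        a <- suppressWarnings(as.numeric(a))
        if (all(is.na(a)) || sum(a, na.rm = TRUE) == 0) return(NA_real_)
        min(a, na.rm = TRUE) / sum(a, na.rm = TRUE)
      }, numeric(1))
    })
    if (is.null(dim(minorFrac)))
      minorFrac <- matrix(minorFrac, nrow = sum(keep),
                          dimnames = list(NULL, colnames(gt)))
  }
  lens <- numeric()
  cl <- grep("^##contig", v@meta, value = TRUE)
  if (length(cl)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", cl)
    lns <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", cl)))
    lens <- setNames(lns, ids)
    lens <- lens[!is.na(lens)]
  }
  GenotypeMatrix(geno, chrom = fix[keep, "CHROM"],
                 pos = as.integer(fix[keep, "POS"]),
                 popMap = popMap, ploidy = ploidy, chromLengths = lens,
                 depth = depth, minorFrac = minorFrac)
}

#' Write a GenotypeMatrix as a minimal VCF
#'
#' Emits biallelic records (REF=A, ALT=T for variant sites; ALT="." for
#' invariant ones), diploid GT fields (haploid matrices written as
#' homozygous), and `##contig` headers carrying chromosome lengths.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGenotypeVcf <- function(gm, path) {
  samples <- colnames(gm@geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ygeneflow",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (length(gm@chromLengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(gm@chromLengths),
                       as.integer(gm@chromLengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  variant <- rowSums(gm@geno, na.rm = TRUE) > 0
  gtCode <- function(d) {
    if (gm@ploidy == 1L)
      c("0/0", "1/1", "./.")[ifelse(is.na(d), 3L, d + 1L)]
    else
      c("0/0", "0/1", "1/1", "./.")[ifelse(is.na(d), 4L, d + 1L)]
  }
  gtMat <- apply(gm@geno, 2, gtCode)
  if (is.null(dim(gtMat)))
    gtMat <- matrix(gtMat, nrow = nrow(gm@geno),
                    dimnames = list(NULL, samples))
  lines <- paste(gm@chrom, gm@pos, ".", "A",
                 ifelse(variant, "T", "."), ".", "PASS", ".", "GT",
                 apply(gtMat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
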