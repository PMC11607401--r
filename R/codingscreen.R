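# Screen coding genes for amino-acid differences fixed between the
# introgressed-Y clade and the ancestral-Y clade, excluding genes with
# internal stop codons in any focal sample.

#' Translate a coding sequence
#'
#' Standard genetic code, frame anchored at position 1. Alignment gaps and
#' ambiguity codes translate to `X`; a stop codon before the final codon
#' sets the internal-stop flag.
#'
#' @param sequence A character string, `Biostrings::DNAString`, or similar;
#'   length must be divisible by 3.
#' @param gene Optional gene name used in error messages.
#' @return A list with `aa` (amino-acid string, possibly ending in `*`) and
#'   `internalStop` (logical).
#' @export
#' @examples
#' translateCds("ATGAAATGA")$aa          # "MK*"
#' translateCds("ATGTAAAAA")$internalStop
translateCds <- function(sequence, gene = "<cds>") {
  s <- toupper(as.character(sequence))
  if (nchar(s) %% 3 != 0)
    stop(sprintf("CDS length of gene '%s' (%d) is not divisible by 3",
                 gene, nchar(s)), call. = FALSE)
  s <- gsub("[-.]", "N", s)   # gap columns become ambiguous -> X
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  nAA <- nchar(aa)
  internal <- nAA > 1 && grepl("\\*", substr(aa, 1, nAA - 1))
  list(aa = aa, internalStop = internal)
}

#' Count fixed amino-acid differences between two clades
#'
#' A position counts if and only if every non-missing clade-A residue is
#' identical, every non-missing clade-B residue is identical, the two
#' residues differ, and each clade has at least one non-missing call.
#' `X`, `-` and `*`-past-the-end never count as calls.
#'
#' @param aa Named character vector of aligned amino-acid sequences (equal
#'   length).
#' @param cladeA,cladeB Sample names in `names(aa)` (non-empty, disjoint).
#' @return A list with `count`, `positions` (1-based alignment positions),
#'   and `residues` (data.frame position/cladeA/cladeB).
#' @export
fixedAaDifferences <- function(aa, cladeA, cladeB) {
  .check(length(cladeA) >= 1 && length(cladeB) >= 1,
         "both clades must contain at least one sample")
  .check(all(c(cladeA, cladeB) %in% names(aa)),
         "clade samples missing from the alignment")
  lens <- nchar(aa[c(cladeA, cladeB)])
  .check(length(unique(lens)) == 1, "aligned sequences differ in length")
  toMat <- function(samples)
    do.call(rbind, strsplit(unname(aa[samples]), ""))
  A <- toMat(cladeA); B <- toMat(cladeB)
  miss <- c("X", "-", ".", "*")
  fixedResidue <- function(col) {
    col <- col[!(col %in% miss)]
    if (!length(col)) return(NA_character_)
    u <- unique(col)
    if (length(u) == 1) u else "."  # polymorphic sentinel (never matches)
  }
  resA <- apply(A, 2, fixedResidue)
  resB <- apply(B, 2, fixedResidue)
  hit <- !is.na(resA) & !is.na(resB) & resA != "." & resB != "." &
    resA != resB
  list(count = sum(hit), positions = which(hit),
       residues = data.frame(position = which(hit),
                             cladeA = resA[hit], cladeB = resB[hit]))
}

#' Screen per-gene CDS alignments for clade-fixed amino-acid differences
#'
#' Reads one FASTA alignment per gene, translates every sample, excludes
#' genes carrying an internal stop codon in any focal (clade A or B)
#' sample, and counts fixed amino-acid differences between the clades.
#'
#' @param fastaFiles Named character vector of FASTA paths (names are gene
#'   ids; otherwise file basenames are used).
#' @param cladeA,cladeB Sample name vectors (sequence names in the FASTA).
#' @return data.frame with one row per gene: `gene`, `nFixed`, `positions`
#'   (comma-separated), `excluded`, `reason`.
#' @export
codingScreen <- function(fastaFiles, cladeA, cladeB) {
  genes <- names(fastaFiles)
  if (is.null(genes))
    genes <- sub("\\.(fa|fasta|fna)$", "", basename(fastaFiles))
  rows <- lapply(seq_along(fastaFiles), function(i) {
    seqs <- Biostrings::readDNAStringSet(fastaFiles[[i]])
    focal <- intersect(names(seqs), c(cladeA, cladeB))
    tr <- lapply(setNames(focal, focal), function(s)
      translateCds(seqs[[s]], gene = genes[i]))
    stops <- vapply(tr, `[[`, logical(1), "internalStop")
    if (any(stops))
      return(data.frame(gene = genes[i], nFixed = NA_integer_,
                        positions = "", excluded = TRUE,
                        reason = paste0("internal stop in ",
                                        paste(focal[stops],
                                              collapse = ","))))
    aa <- vapply(tr, `[[`, character(1), "aa")
    fd <- fixedAaDifferences(aa, intersect(cladeA, focal),
                             intersect(cladeB, focal))
    data.frame(gene = genes[i], nFixed = fd$count,
               positions = paste(fd$positions, collapse = ","),
               excluded = FALSE, reason = "")
  })
  do.call(rbind, rows)
}
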