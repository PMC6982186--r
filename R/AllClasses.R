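#' @import methods
#' @importFrom S4Vectors DataFrame DFrame metadata metadata<- isSingleNumber
#' @importFrom stats rpois runif rbinom rnorm pchisq quantile sd setNames
#' @importFrom utils read.delim write.table head
NULL

.SNP_DEPTH_COLS <- c("chrom", "pos", "ref", "alt",
                     "L_ref", "L_alt", "S_ref", "S_alt")

#' Per-SNP allele depths for two phenotype bulks
#'
#' A \linkS4class{DFrame} subclass holding one biallelic SNP per row with
#' reference/alternate read depths for the long-phenotype (L) and
#' short-phenotype (S) bulks.  The alternate allele is, by the package's
#' polarization convention, the short-parent allele; a SNP index of 0 then
#' means every read matched the reference (long-parent) allele.
#'
#' @slot .Data inherited from \code{DFrame}; columns \code{chrom, pos, ref,
#'   alt, L_ref, L_alt, S_ref, S_alt}.
#' @seealso [snpDepthTable()], [simulateBulkDepths()], [readSnpDepth()]
#' @export
setClass("SnpDepthTable", contains = "DFrame")

setValidity("SnpDepthTable", function(object) {
  msg <- character()
  miss <- setdiff(.SNP_DEPTH_COLS, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(object)) {
    depth <- as.matrix(as.data.frame(
      object[, c("L_ref", "L_alt", "S_ref", "S_alt")]))
    if (any(is.na(depth)) || any(depth < 0))
      msg <- c(msg, "read depths must be non-negative and non-missing")
    if (any(object$pos < 1))
      msg <- c(msg, "positions must be >= 1 (1-based)")
    bad <- nchar(object$ref) != 1L | nchar(object$alt) != 1L |
      object$ref == object$alt
    if (any(bad))
      msg <- c(msg, "ref/alt must be distinct single bases")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpDepthTable
#'
#' @param x a data.frame (or DataFrame) with columns \code{chrom, pos, ref,
#'   alt, L_ref, L_alt, S_ref, S_alt}.
#' @return a \linkS4class{SnpDepthTable}
#' @examples
#' snpDepthTable(data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T",
#'                          L_ref = 12, L_alt = 18, S_ref = 30, S_alt = 0))
#' @export
snpDepthTable <- function(x) {
  df <- DataFrame(x)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  for (cc in c("L_ref", "L_alt", "S_ref", "S_alt"))
    df[[cc]] <- as.integer(df[[cc]])
  new("SnpDepthTable", df[, .SNP_DEPTH_COLS])
}

#' Sliding-window SNP-index profile
#'
#' One row per window: per-pool mean SNP indices, the delta SNP index
#' (L minus S), the number of contributing SNPs, the window's effective read
#' depth, and (after [attachNullCI()]) the null confidence bounds.
#'
#' @slot windowSize window width in bp
#' @slot step window increment in bp
#' @export
setClass("WindowProfile", contains = "DFrame",
         representation(windowSize = "numeric", step = "numeric"))

setValidity("WindowProfile", function(object) {
  need <- c("chrom", "start", "end", "n_snps", "index_L", "index_S",
            "delta", "eff_depth", "ci_lower", "ci_upper")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(object)) {
    i <- c(object$index_L, object$index_S)
    if (any(i < 0 | i > 1, na.rm = TRUE))
      return("window mean indices must lie in [0, 1]")
    if (any(abs(object$delta) > 1, na.rm = TRUE))
      return("delta SNP index must lie in [-1, 1]")
    with_snps <- object$n_snps > 0
    if (any(is.na(object$index_L[with_snps])) ||
        any(is.na(object$index_S[with_snps])))
      return("windows with SNPs must carry indices")
  }
  TRUE
})

#' Null confidence bounds for the delta SNP index, by read depth
#'
#' Empirical quantile bounds of the single-SNP delta SNP index simulated
#' under the no-locus null (F2 bulk composition resampled, then reads),
#' tabulated per read depth and confidence level.
#'
#' @slot reps simulation replicates per depth
#' @slot bulkSize individuals per bulk in the null model
#' @slot seed seed the table was generated under
#' @export
setClass("NullCiTable", contains = "DFrame",
         representation(reps = "integer", bulkSize = "integer",
                        seed = "integer"))

setValidity("NullCiTable", function(object) {
  need <- c("depth", "level", "lower", "upper")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (object@reps < 1L) return("reps must be >= 1")
  if (nrow(object) && any(object$lower > 0 | object$upper < 0))
    return("null bounds must bracket 0")
  TRUE
})

#' Chi-square goodness-of-fit result for a segregation ratio
#'
#' @slot observed observed class counts
#' @slot expectedRatio the tested ratio weights
#' @slot chi2 Pearson statistic
#' @slot df degrees of freedom (classes minus one)
#' @slot p upper-tail p-value
#' @seealso [chiSquareGof()], [testStandardRatios()]
#' @export
setClass("SegregationResult",
         representation(observed = "integer", expectedRatio = "numeric",
                        chi2 = "numeric", df = "integer", p = "numeric"))

setValidity("SegregationResult", function(object) {
  if (object@df != length(object@observed) - 1L)
    return("df must equal number of classes minus one")
  if (object@chi2 < 0) return("chi2 must be non-negative")
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  TRUE
})

#' Individuals-by-markers genotype table with phenotypes
#'
#' Genotype codes: \code{A} homozygous long-parent, \code{H} heterozygous,
#' \code{B} homozygous short-parent, \code{NA} missing.  Phenotypes are
#' \code{"long"} or \code{"short"}.  Markers are kept sorted by position.
#'
#' @slot genotypes character matrix, individuals x markers
#' @slot markers DFrame with columns \code{name, chrom, pos}
#' @slot phenotype character vector, one entry per individual
#' @export
setClass("MarkerGenotypeTable",
         representation(genotypes = "matrix", markers = "DFrame",
                        phenotype = "character"))

setValidity("MarkerGenotypeTable", function(object) {
  g <- object@genotypes
  if (!is.character(g)) return("genotype codes must be character")
  if (ncol(g) != nrow(object@markers))
    return("genotype columns must match marker rows")
  if (nrow(g) != length(object@phenotype))
    return("one phenotype per individual is required")
  if (any(is.na(object@phenotype)))
    return("phenotype present for all individuals")
  if (!all(object@phenotype %in% c("long", "short")))
    return("phenotypes must be 'long' or 'short'")
  if (!all(g %in% c("A", "H", "B", NA)))
    return("genotype codes must be A, H, B or NA")
  if (nrow(object@markers) > 1) {
    o <- order(object@markers$chrom, object@markers$pos)
    if (!identical(o, seq_len(nrow(object@markers))))
      return("markers must be sorted by chromosome and position")
  }
  TRUE
})

#' Fine-mapping interval between contradicted flanking markers
#'
#' @slot leftMarker,rightMarker names of the flanking markers
#' @slot start,end physical bounds in bp (1-based)
#' @slot length \code{end - start} in bp
#' @slot nRecombinants distinct individuals contradicting a flanking marker
#' @export
setClass("IntervalResult",
         representation(leftMarker = "character", rightMarker = "character",
                        start = "numeric", end = "numeric",
                        length = "numeric", nRecombinants = "integer"))

setValidity("IntervalResult", function(object) {
  if (object@start >= object@end) return("start must be < end")
  if (object@length != object@end - object@start)
    return("length must equal end - start")
  TRUE
})

#' Predicted coding consequence of a deletion
#'
#' @slot deletionStart,deletionEnd 1-based inclusive bp on the reference CDS
#' @slot deletedLength bp removed
#' @slot frameshift TRUE iff deleted length is not a multiple of 3
#' @slot stopCodonPosition 1-based bp of the first stop codon on the mutant
#'   CDS, or NA when translation runs off the end
#' @slot proteinLengthRef,proteinLengthMut residues before the first stop
#' @slot lostDomains DFrame of domains truncated away
#'   (columns \code{name, start_aa, end_aa, partial})
#' @export
setClass("CodingEffect",
         representation(deletionStart = "integer", deletionEnd = "integer",
                        deletedLength = "integer", frameshift = "logical",
                        stopCodonPosition = "integer",
                        proteinLengthRef = "integer",
                        proteinLengthMut = "integer",
                        lostDomains = "DFrame"))

setValidity("CodingEffect", function(object) {
  if (object@deletedLength != object@deletionEnd - object@deletionStart + 1L)
    return("deletedLength must equal end - start + 1")
  if (object@frameshift != (object@deletedLength %% 3L != 0L))
    return("frameshift flag inconsistent with deleted length")
  if (!is.na(object@stopCodonPosition) &&
      object@proteinLengthMut > object@proteinLengthRef)
    return("premature stop cannot lengthen the protein")
  TRUE
})

#' Simulated F2 population
#'
#' Genotypes count short-parent alleles (0/1/2) at each simulated SNP;
#' phenotype is recessive at the causal locus (short iff code 2 there).
#'
#' @slot genotypes integer matrix, individuals x SNPs (0/1/2)
#' @slot snpInfo DFrame with columns \code{chrom, pos}
#' @slot phenotype character vector, "long"/"short"
#' @slot causalChrom,causalPos the planted causal locus
#' @slot map the \linkS4class{GeneticMap} the population was simulated on
#' @export
setClass("F2Population",
         representation(genotypes = "matrix", snpInfo = "DFrame",
                        phenotype = "character", causalChrom = "character",
                        causalPos = "numeric", map = "ANY"))

setValidity("F2Population", function(object) {
  g <- object@genotypes
  if (!all(g %in% 0:2)) return("genotype codes must be 0, 1 or 2")
  if (ncol(g) != nrow(object@snpInfo))
    return("genotype columns must match snpInfo rows")
  if (nrow(g) != length(object@phenotype))
    return("one phenotype per individual")
  ci <- which(object@snpInfo$chrom == object@causalChrom &
              object@snpInfo$pos == object@causalPos)
  if (length(ci) != 1L) return("causal locus must be a simulated SNP")
  if (!all((object@phenotype == "short") == (g[, ci] == 2L)))
    return("phenotype must be recessive at the causal locus")
  TRUE
})

#' Genetic map for the F2 simulator
#'
#' @slot chromosomes DFrame with columns \code{name, length_bp, length_m}
#'   (physical length in bp, genetic length in Morgans)
#' @slot snpPositions named list of sorted SNP positions per chromosome
#' @slot markerPositions named list of fine-mapping marker positions
#'   (a subset of the SNP positions)
#' @export
setClass("GeneticMap",
         representation(chromosomes = "DFrame", snpPositions = "list",
                        markerPositions = "list"))

setValidity("GeneticMap", function(object) {
  ch <- object@chromosomes
  need <- c("name", "length_bp", "length_m")
  if (!all(need %in% colnames(ch)))
    return("chromosomes needs columns name, length_bp, length_m")
  if (any(ch$length_m < 0)) return("genetic length must be >= 0")
  for (nm in ch$name) {
    p <- object@snpPositions[[nm]]
    if (is.null(p) || !length(p)) next
    if (is.unsorted(p, strictly = TRUE))
      return(paste0("SNP positions on ", nm, " must be strictly increasing"))
    if (max(p) > ch$length_bp[ch$name == nm])
      return(paste0("SNP positions on ", nm, " exceed chromosome length"))
    m <- object@markerPositions[[nm]]
    if (!is.null(m) && !all(m %in% p))
      return(paste0("marker positions on ", nm, " must be SNP positions"))
  }
  TRUE
})
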