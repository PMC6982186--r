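#' @describeIn SegregationResult-class observed counts
#' @param x,object a SegregationResult
#' @export
setGeneric("observedCounts", function(x) standardGeneric("observedCounts"))

#' @rdname SegregationResult-class
#' @export
setMethod("observedCounts", "SegregationResult", function(x) x@observed)

#' @rdname SegregationResult-class
#' @export
setGeneric("chi2", function(x) standardGeneric("chi2"))

#' @rdname SegregationResult-class
#' @export
setMethod("chi2", "SegregationResult", function(x) x@chi2)

#' @rdname SegregationResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname SegregationResult-class
#' @export
setMethod("pValue", "SegregationResult", function(x) x@p)

setMethod("show", "SegregationResult", function(object) {
  cat(sprintf(
    "Segregation test vs ratio %s: observed (%s), chi2 = %.4g, df = %d, p = %.4g\n",
    paste(object@expectedRatio, collapse = ":"),
    paste(object@observed, collapse = ", "),
    object@chi2, object@df, object@p))
})

#' @rdname F2Population-class
#' @param x,object an F2Population
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname F2Population-class
#' @export
setMethod("phenotypes", "F2Population", function(x) x@phenotype)

#' @rdname MarkerGenotypeTable-class
#' @export
setMethod("phenotypes", "MarkerGenotypeTable", function(x) x@phenotype)

#' @rdname F2Population-class
#' @export
setGeneric("genotypeCodes", function(x) standardGeneric("genotypeCodes"))

#' @rdname F2Population-class
#' @export
setMethod("genotypeCodes", "F2Population", function(x) x@genotypes)

#' @rdname MarkerGenotypeTable-class
#' @param x a MarkerGenotypeTable
#' @export
setMethod("genotypeCodes", "MarkerGenotypeTable", function(x) x@genotypes)

#' @rdname MarkerGenotypeTable-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname MarkerGenotypeTable-class
#' @export
setMethod("markerInfo", "MarkerGenotypeTable", function(x) x@markers)

#' @rdname F2Population-class
#' @export
setGeneric("causalLocus", function(x) standardGeneric("causalLocus"))

#' @rdname F2Population-class
#' @export
setMethod("causalLocus", "F2Population",
          function(x) list(chrom = x@causalChrom, pos = x@causalPos))

setMethod("show", "F2Population", function(object) {
  tab <- table(factor(object@phenotype, c("long", "short")))
  cat(sprintf(
    "F2Population: %d individuals, %d SNPs on %d chromosome(s)\n",
    nrow(object@genotypes), ncol(object@genotypes),
    length(unique(object@snpInfo$chrom))))
  cat(sprintf("  phenotypes: %d long, %d short; causal locus %s:%d\n",
              tab[["long"]], tab[["short"]], object@causalChrom,
              as.integer(object@causalPos)))
})

setMethod("show", "MarkerGenotypeTable", function(object) {
  cat(sprintf("MarkerGenotypeTable: %d individuals x %d markers\n",
              nrow(object@genotypes), ncol(object@genotypes)))
  if (nrow(object@markers))
    cat("  markers:", paste(head(object@markers$name, 8), collapse = ", "),
        if (nrow(object@markers) > 8) "..." else "", "\n")
})

setMethod("show", "SnpDepthTable", function(object) {
  cat(sprintf("SnpDepthTable: %d SNPs on %d chromosome(s)\n",
              nrow(object), length(unique(object$chrom))))
  callNextMethod()
})

setMethod("show", "WindowProfile", function(object) {
  cat(sprintf("WindowProfile: %d windows (size %g bp, step %g bp)\n",
              nrow(object), object@windowSize, object@step))
  callNextMethod()
})

setMethod("show", "NullCiTable", function(object) {
  cat(sprintf(
    "NullCiTable: %d depth x level combinations (%d reps, bulk size %d)\n",
    nrow(object), object@reps, object@bulkSize))
  callNextMethod()
})

setMethod("show", "IntervalResult", function(object) {
  cat(sprintf(
    "Fine-mapping interval %s..%s: %s-%s (%s bp, %.3f kb), %d recombinant(s)\n",
    object@leftMarker, object@rightMarker,
    format(object@start, big.mark = ",", scientific = FALSE),
    format(object@end, big.mark = ",", scientific = FALSE),
    format(object@length, big.mark = ",", scientific = FALSE),
    object@length / 1000,
    object@nRecombinants))
})

#' @rdname IntervalResult-class
#' @param x an IntervalResult
#' @export
setGeneric("intervalLength", function(x) standardGeneric("intervalLength"))

#' @rdname IntervalResult-class
#' @export
setMethod("intervalLength", "IntervalResult", function(x) x@length)

#' @rdname IntervalResult-class
#' @export
setGeneric("flankingMarkers", function(x) standardGeneric("flankingMarkers"))

#' @rdname IntervalResult-class
#' @export
setMethod("flankingMarkers", "IntervalResult",
          function(x) c(left = x@leftMarker, right = x@rightMarker))

setMethod("show", "CodingEffect", function(object) {
  cat(sprintf("CodingEffect: %d bp deletion at %d-%d (%s)\n",
              object@deletedLength, object@deletionStart, object@deletionEnd,
              if (object@frameshift) "frameshift" else "in-frame"))
  cat(sprintf("  protein: %d aa (reference) -> %d aa (mutant)%s\n",
              object@proteinLengthRef, object@proteinLengthMut,
              if (!is.na(object@stopCodonPosition))
                sprintf(", stop codon at mutant bp %d",
                        object@stopCodonPosition) else ""))
  if (nrow(object@lostDomains))
    cat("  lost domains:",
        paste0(object@lostDomains$name,
               ifelse(object@lostDomains$partial, " (partial)", "")),
        "\n")
  else cat("  lost domains: none\n")
})

#' @rdname CodingEffect-class
#' @param x a CodingEffect
#' @export
setGeneric("isFrameshift", function(x) standardGeneric("isFrameshift"))

#' @rdname CodingEffect-class
#' @export
setMethod("isFrameshift", "CodingEffect", function(x) x@frameshift)

#' @rdname CodingEffect-class
#' @export
setGeneric("proteinLengths", function(x) standardGeneric("proteinLengths"))

#' @rdname CodingEffect-class
#' @export
setMethod("proteinLengths", "CodingEffect",
          function(x) c(reference = x@proteinLengthRef,
                        mutant = x@proteinLengthMut))

#' @rdname CodingEffect-class
#' @export
setGeneric("lostDomains", function(x) standardGeneric("lostDomains"))

#' @rdname CodingEffect-class
#' @export
setMethod("lostDomains", "CodingEffect", function(x) x@lostDomains)

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d chromosome(s), %d SNPs, %d markers\n",
              nrow(object@chromosomes),
              sum(lengths(object@snpPositions)),
              sum(lengths(object@markerPositions))))
})
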