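#' Delete a stretch of bases from a CDS
#'
#' Coordinates are 1-based inclusive on the input sequence, so a deletion
#' spanning 502-514 removes 13 bases.
#'
#' @param cds DNA sequence (character or DNAString)
#' @param start,end 1-based inclusive deletion bounds
#' @return the sequence with positions start..end removed (character)
#' @export
applyDeletion <- function(cds, start, end) {
  cds <- as.character(cds)
  n <- nchar(cds)
  if (start < 1 || end > n || start > end)
    stop("deletion coordinates ", start, "-", end,
         " out of range for a ", n, " bp sequence")
  paste0(substr(cds, 1, start - 1), substr(cds, end + 1, n))
}

#' Translate a CDS, halting at the first stop codon
#'
#' Standard genetic code, codons read from position 1; the first stop codon
#' terminates translation and is not included; a trailing partial codon is
#' ignored. Sequences shorter than one codon return an empty protein with a
#' warning.
#'
#' @param cds DNA sequence (character or DNAString), A/C/G/T only
#' @return protein sequence as a character string
#' @examples
#' translateCds("ATGAAATAA")  # "MK"
#' @export
translateCds <- function(cds) {
  cds <- .checkDna(cds, "CDS")
  n <- nchar(cds)
  if (n < 3) {
    warning("sequence shorter than one codon; empty protein returned")
    return("")
  }
  starts <- seq(1, n - 2, by = 3)
  codons <- substring(cds, starts, starts + 2)
  aa <- Biostrings::GENETIC_CODE[codons]
  stopAt <- which(aa == "*")
  if (length(stopAt)) aa <- aa[seq_len(stopAt[1] - 1L)]
  paste(aa, collapse = "")
}

# 1-based bp position of the first stop codon, or NA if translation runs
# off the end of the sequence.
.firstStopBp <- function(cds) {
  n <- nchar(cds)
  if (n < 3) return(NA_integer_)
  starts <- seq(1, n - 2, by = 3)
  codons <- substring(cds, starts, starts + 2)
  hit <- which(codons %in% .STOP_CODONS)
  if (length(hit)) as.integer(starts[hit[1]]) else NA_integer_
}

#' Classify the coding consequence of a deletion
#'
#' Reports frameshift status (deleted length not a multiple of 3), the
#' reference and mutant protein lengths (translation up to the first stop),
#' the position of the first stop codon on the mutant CDS, and which
#' annotated protein domains are truncated away. A domain is lost iff its
#' last residue exceeds the mutant protein length; a domain that starts
#' before the truncation point is flagged partial.
#'
#' @param refCds reference CDS (character or DNAString)
#' @param mutantCds mutant CDS, or NULL to derive it from the deletion
#' @param deletionStart,deletionEnd 1-based inclusive bp on the reference
#' @param domains optional data.frame/DFrame with columns \code{name},
#'   \code{start_aa}, \code{end_aa} (1-based residue coordinates on the
#'   reference protein)
#' @return a \linkS4class{CodingEffect}
#' @examples
#' fx <- makeCdsFixture(seed = 7)
#' classifyEffect(fx$ref, fx$mut, 502, 514, fx$domains)
#' @export
classifyEffect <- function(refCds, mutantCds = NULL, deletionStart,
                           deletionEnd, domains = NULL) {
  refCds <- .checkDna(refCds, "reference CDS")
  delLen <- as.integer(deletionEnd - deletionStart + 1L)
  derived <- applyDeletion(refCds, deletionStart, deletionEnd)
  if (is.null(mutantCds)) {
    mutantCds <- derived
  } else {
    mutantCds <- .checkDna(mutantCds, "mutant CDS")
    if (nchar(mutantCds) != nchar(refCds) - delLen)
      stop("mutant length inconsistent with a ", delLen, " bp deletion")
    if (mutantCds != derived)
      stop("mutant CDS does not equal the reference with the stated ",
           "deletion applied")
  }
  protRef <- translateCds(refCds)
  protMut <- translateCds(mutantCds)
  lenRef <- nchar(protRef); lenMut <- nchar(protMut)
  lost <- DataFrame(name = character(), start_aa = integer(),
                    end_aa = integer(), partial = logical())
  if (!is.null(domains) && NROW(domains)) {
    domains <- DataFrame(domains)
    if (any(domains$start_aa < 1 | domains$start_aa > domains$end_aa |
            domains$end_aa > lenRef))
      stop("domain coordinates must satisfy 1 <= start <= end <= ",
           lenRef, " (reference protein length)")
    isLost <- domains$end_aa > lenMut
    lost <- DataFrame(name = as.character(domains$name[isLost]),
                      start_aa = as.integer(domains$start_aa[isLost]),
                      end_aa = as.integer(domains$end_aa[isLost]),
                      partial = domains$start_aa[isLost] <= lenMut)
  }
  new("CodingEffect",
      deletionStart = as.integer(deletionStart),
      deletionEnd = as.integer(deletionEnd),
      deletedLength = delLen,
      frameshift = delLen %% 3L != 0L,
      stopCodonPosition = .firstStopBp(mutantCds),
      proteinLengthRef = lenRef, proteinLengthMut = lenMut,
      lostDomains = lost)
}
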