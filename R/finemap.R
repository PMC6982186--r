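.checkDna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  if (!grepl("^[ACGT]*$", x))
    stop(what, " contains characters other than A/C/G/T")
  x
}

#' In-silico restriction digest of an amplicon
#'
#' Scans the forward strand of the uncut amplicon left to right and cuts
#' after base \code{siteStart + cutOffset - 1} at every occurrence of the
#' recognition sequence (overlapping occurrences all cut; typical CAPS
#' enzymes have palindromic sites, so forward-strand scanning suffices).
#'
#' @param amplicon DNA sequence (character or DNAString), A/C/G/T only
#' @param recognition enzyme recognition sequence, e.g. "GAATTC"
#' @param cutOffset bases into the site after which the cut falls
#'   (EcoRI G^AATTC has offset 1); 0..nchar(recognition)
#' @return integer vector of ordered fragment lengths summing to the
#'   amplicon length
#' @examples
#' capsDigest("GAATTCAAA", "GAATTC", 1)  # fragments 1, 8
#' @export
capsDigest <- function(amplicon, recognition, cutOffset) {
  amplicon <- .checkDna(amplicon, "amplicon")
  recognition <- .checkDna(recognition, "recognition site")
  if (!nchar(recognition)) stop("recognition sequence must be non-empty")
  if (nchar(recognition) >= nchar(amplicon))
    stop("recognition sequence must be shorter than the amplicon")
  stopifnot(cutOffset >= 0, cutOffset <= nchar(recognition))
  m <- Biostrings::matchPattern(recognition, Biostrings::DNAString(amplicon))
  cuts <- Biostrings::start(m) + cutOffset - 1L
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < nchar(amplicon)]))
  as.integer(diff(c(0L, cuts, nchar(amplicon))))
}

#' Is a CAPS assay polymorphic between two parental amplicons?
#'
#' @param ampliconA,ampliconB parental amplicon sequences
#' @param recognition,cutOffset as in [capsDigest()]
#' @return list: \code{polymorphic} (TRUE iff the fragment-length multisets
#'   differ), \code{fragmentsA}, \code{fragmentsB}
#' @export
capsPolymorphic <- function(ampliconA, ampliconB, recognition, cutOffset) {
  fa <- capsDigest(ampliconA, recognition, cutOffset)
  fb <- capsDigest(ampliconB, recognition, cutOffset)
  list(polymorphic = !identical(sort(fa), sort(fb)),
       fragmentsA = fa, fragmentsB = fb)
}

.markerColumn <- function(table, marker) {
  j <- match(marker, table@markers$name)
  if (is.na(j)) stop("unknown marker: ", marker)
  table@genotypes[, j]
}

#' Individuals recombinant between two markers
#'
#' @param table a \linkS4class{MarkerGenotypeTable}
#' @param left,right marker names
#' @return ids of individuals with non-missing, unequal codes at the two
#'   markers (missing at either marker excludes the individual)
#' @export
findRecombinants <- function(table, left, right) {
  a <- .markerColumn(table, left)
  b <- .markerColumn(table, right)
  ids <- rownames(table@genotypes)
  if (is.null(ids)) ids <- as.character(seq_along(a))
  ids[!is.na(a) & !is.na(b) & a != b]
}

# Individuals whose code at marker j contradicts the recessive model
# (short phenotype => B; long => A or H). Missing codes never contradict.
.violators <- function(table, j) {
  code <- table@genotypes[, j]
  short <- table@phenotype == "short"
  which(!is.na(code) & ((short & code != "B") | (!short & code == "B")))
}

#' Narrow the causal interval from recombinant individuals
#'
#' A marker is consistent with the causal position iff no individual
#' contradicts the recessive model there (short implies B; long implies A
#' or H). The interval is bounded by the nearest markers flanking the
#' consistent block that are each contradicted by at least one recombinant;
#' where no contradicted marker exists on a side, the outermost marker
#' bounds the interval. When the causal locus falls strictly between two
#' markers (no marker fully consistent), the interval is the adjacent
#' marker pair contradicted by the fewest distinct recombinants; if even
#' that pair is contradicted by more than a quarter of the individuals the
#' trait is declared unlinked. Length is \code{end - start} in bp.
#'
#' @param table a \linkS4class{MarkerGenotypeTable} (markers on one
#'   chromosome)
#' @param traitModel only \code{"recessive"} is supported
#' @return an \linkS4class{IntervalResult}
#' @export
narrowInterval <- function(table, traitModel = "recessive") {
  traitModel <- match.arg(traitModel, "recessive")
  mk <- table@markers
  if (nrow(mk) < 2) stop("at least two markers are required")
  if (length(unique(mk$chrom)) > 1)
    stop("fine-mapping markers must lie on a single chromosome")
  viol <- lapply(seq_len(nrow(mk)), function(j) .violators(table, j))
  consistent <- lengths(viol) == 0L
  if (any(consistent)) {
    # longest run of consistent markers (ties: leftmost)
    r <- rle(consistent)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    pick <- runs[which.max(r$lengths[runs])]
    lo <- starts[pick]; hi <- ends[pick]
    left <- if (lo > 1) lo - 1L else 1L
    right <- if (hi < nrow(mk)) hi + 1L else nrow(mk)
  } else {
    # causal locus between two markers: violations accumulate with distance
    # from the causal position, so the true gap minimizes the distinct
    # recombinants contradicting its two flanks (shared violators would
    # need double crossovers and stay rare under linkage)
    unions <- vapply(seq_len(nrow(mk) - 1L), function(j)
      length(unique(c(viol[[j]], viol[[j + 1L]]))), 1L)
    best <- which.min(unions)
    # an unlinked trait contradicts every marker in a large fraction of
    # individuals; a linked one only in the rare gap recombinants
    if (unions[best] > 0.25 * nrow(table@genotypes))
      stop("trait not linked to supplied markers")
    left <- best
    right <- best + 1L
  }
  recomb <- unique(unlist(viol[c(left, right)]))
  new("IntervalResult",
      leftMarker = mk$name[left], rightMarker = mk$name[right],
      start = as.numeric(mk$pos[left]), end = as.numeric(mk$pos[right]),
      length = as.numeric(mk$pos[right] - mk$pos[left]),
      nRecombinants = length(recomb))
}

#' Co-segregation summary for one marker
#'
#' Genotype class counts, concordance with the recessive phenotype model
#' (code B iff phenotype short), and a chi-square test against 1:2:1.
#'
#' @param table a \linkS4class{MarkerGenotypeTable}
#' @param marker marker name
#' @return list: \code{counts} (named A/H/B), \code{concordance} (fraction
#'   of non-missing individuals fitting the recessive model),
#'   \code{segregation} (a \linkS4class{SegregationResult} vs 1:2:1)
#' @examples
#' ## the classic 33/67/35 split in 135 F2 plants fits 1:2:1 closely
#' @export
cosegregationSummary <- function(table, marker) {
  code <- .markerColumn(table, marker)
  ok <- !is.na(code)
  counts <- c(A = sum(code[ok] == "A"), H = sum(code[ok] == "H"),
              B = sum(code[ok] == "B"))
  short <- table@phenotype == "short"
  concord <- mean((code[ok] == "B") == short[ok])
  list(counts = counts, concordance = concord,
       segregation = chiSquareGof(counts, c(1, 2, 1)))
}
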