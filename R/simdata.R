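#' Build a genetic map for the F2 simulator
#'
#' @param chromosomes data.frame with columns \code{name}, \code{length_bp}
#'   (physical length), \code{length_m} (genetic length in Morgans).
#' @param snpPositions named list (one entry per chromosome) of strictly
#'   increasing SNP positions in bp.
#' @param markerPositions named list of fine-mapping marker positions; each
#'   must also be a SNP position. Default: no markers.
#' @return a \linkS4class{GeneticMap}
#' @export
geneticMap <- function(chromosomes, snpPositions, markerPositions = list()) {
  ch <- DataFrame(chromosomes)
  ch$name <- as.character(ch$name)
  new("GeneticMap", chromosomes = ch,
      snpPositions = lapply(snpPositions, as.numeric),
      markerPositions = lapply(markerPositions, as.numeric))
}

#' Default simulation design: 3 chromosomes, 30 Mb / 1.2 Morgans each
#'
#' SNPs every \code{snpSpacing} bp on every chromosome. Fine-mapping
#' markers sit on the causal chromosome: a ladder around the causal
#' position (every 500 kb within +/- 2.5 Mb) plus one marker at the causal
#' position itself, mimicking a gene-internal indel marker.
#'
#' @param nChrom number of chromosomes
#' @param lengthBp,lengthM physical and genetic length per chromosome
#' @param snpSpacing distance between simulated SNPs in bp
#' @param causalChrom,causalPos the causal locus (must fall on the SNP grid)
#' @return a \linkS4class{GeneticMap}; the causal locus is stored in the
#'   map's metadata-free convention by the caller of [simulateF2()].
#' @export
defaultGeneticMap <- function(nChrom = 3, lengthBp = 30e6, lengthM = 1.2,
                              snpSpacing = 5e4, causalChrom = "chr3",
                              causalPos = 15e6) {
  nms <- paste0("chr", seq_len(nChrom))
  snps <- setNames(rep(list(seq(snpSpacing, lengthBp, by = snpSpacing)), nChrom),
                   nms)
  stopifnot(causalChrom %in% nms, causalPos %in% snps[[causalChrom]])
  ladder <- causalPos + seq(-2.5e6, 2.5e6, by = 5e5)
  ladder <- ladder[ladder >= snpSpacing & ladder <= lengthBp]
  markers <- setNames(vector("list", nChrom), nms)
  markers[[causalChrom]] <- sort(unique(c(ladder, causalPos)))
  geneticMap(data.frame(name = nms, length_bp = lengthBp, length_m = lengthM),
             snps, markers)
}

# One gamete: mosaic of parental haplotypes under Haldane's model
# (Poisson crossover count, uniform breakpoints, no interference).
# Returns 0/1 per SNP: 1 = short-parent allele.
.simulateGamete <- function(map) {
  ch <- map@chromosomes
  out <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    pos <- map@snpPositions[[ch$name[i]]]
    nco <- rpois(1L, ch$length_m[i])
    breaks <- sort(runif(nco, 0, ch$length_bp[i]))
    startPar <- sample(0:1, 1L)
    out[[i]] <- (startPar + findInterval(pos, breaks)) %% 2L
  }
  unlist(out, use.names = FALSE)
}

#' Simulate an F2 population segregating for a recessive locus
#'
#' Each individual is formed from two independent gametes; each gamete is a
#' mosaic of the two parental haplotypes with crossover count per chromosome
#' drawn Poisson(genetic length in Morgans) and breakpoints uniform on the
#' physical length (Haldane's model, no interference). The phenotype is
#' recessive: "short" iff the individual is homozygous for the short-parent
#' allele at the causal locus.
#'
#' @param map a \linkS4class{GeneticMap}
#' @param causalChrom,causalPos the causal locus; must be a simulated SNP
#' @param n number of F2 individuals
#' @param seed integer seed; identical seeds give identical populations
#' @return an \linkS4class{F2Population}
#' @examples
#' map <- defaultGeneticMap()
#' pop <- simulateF2(map, "chr3", 15e6, n = 50, seed = 1)
#' table(phenotypes(pop))
#' @export
simulateF2 <- function(map, causalChrom, causalPos, n, seed) {
  stopifnot(is(map, "GeneticMap"), n >= 1)
  ch <- map@chromosomes
  snpInfo <- DataFrame(
    chrom = rep(ch$name, lengths(map@snpPositions[ch$name])),
    pos = unlist(map@snpPositions[ch$name], use.names = FALSE))
  ci <- which(snpInfo$chrom == causalChrom & snpInfo$pos == causalPos)
  if (length(ci) != 1L)
    stop("causal locus ", causalChrom, ":", causalPos,
         " is not a simulated SNP position")
  set.seed(as.integer(seed))
  geno <- matrix(0L, nrow = n, ncol = nrow(snpInfo))
  for (i in seq_len(n))
    geno[i, ] <- .simulateGamete(map) + .simulateGamete(map)
  rownames(geno) <- sprintf("F2_%04d", seq_len(n))
  colnames(geno) <- paste0(snpInfo$chrom, ":", snpInfo$pos)
  phen <- ifelse(geno[, ci] == 2L, "short", "long")
  new("F2Population", genotypes = geno, snpInfo = snpInfo,
      phenotype = unname(phen), causalChrom = causalChrom,
      causalPos = as.numeric(causalPos), map = map)
}

#' Simulate pooled sequencing depths for the two phenotype bulks
#'
#' The long (L) and short (S) bulks take the first \code{bulkSize}
#' individuals of each phenotype (deterministic under the population's
#' seed). Per SNP and pool, the short-parent allele frequency is
#' \eqn{f = \sum g / (2 \cdot bulkSize)} over the pool members' genotype
#' codes; total read depth is drawn per \code{depthModel} and the
#' alternate-read count Binomial(depth, f). The long-parent allele is
#' written as the reference.
#'
#' @param population an \linkS4class{F2Population}
#' @param bulkSize individuals per pool (default 30)
#' @param meanDepth expected reads per SNP per pool (default 30)
#' @param depthModel \code{"poisson"} (default) or \code{"fixed"}
#' @param seed integer seed for depth and read sampling
#' @return a \linkS4class{SnpDepthTable}
#' @export
simulateBulkDepths <- function(population, bulkSize = 30, meanDepth = 30,
                               depthModel = c("poisson", "fixed"), seed) {
  depthModel <- match.arg(depthModel)
  stopifnot(bulkSize >= 1, meanDepth > 0)
  phen <- population@phenotype
  for (ph in c("long", "short")) {
    have <- sum(phen == ph)
    if (have < bulkSize)
      stop("only ", have, " ", ph, "-phenotype individuals available; ",
           bulkSize, " required per bulk")
  }
  idxL <- which(phen == "long")[seq_len(bulkSize)]
  idxS <- which(phen == "short")[seq_len(bulkSize)]
  g <- population@genotypes
  fL <- colSums(g[idxL, , drop = FALSE]) / (2 * bulkSize)
  fS <- colSums(g[idxS, , drop = FALSE]) / (2 * bulkSize)
  nsnp <- ncol(g)
  set.seed(as.integer(seed))
  drawDepth <- function() {
    if (depthModel == "poisson") rpois(nsnp, meanDepth)
    else rep(as.integer(round(meanDepth)), nsnp)
  }
  dL <- drawDepth(); dS <- drawDepth()
  aL <- rbinom(nsnp, dL, fL); aS <- rbinom(nsnp, dS, fS)
  bases <- c("A", "C", "G", "T")
  refb <- sample(bases, nsnp, replace = TRUE)
  altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1L), "")
  snpDepthTable(data.frame(
    chrom = population@snpInfo$chrom, pos = population@snpInfo$pos,
    ref = refb, alt = unname(altb),
    L_ref = dL - aL, L_alt = aL, S_ref = dS - aS, S_alt = aS))
}

#' Extract a marker genotype table from a simulated population
#'
#' @param population an \linkS4class{F2Population}
#' @param markerPositions named list (chromosome -> positions) or NULL to
#'   use the map's marker set. Positions must be simulated SNPs.
#' @param markerNames optional names; default \code{M01, M02, ...} in map
#'   order.
#' @return a \linkS4class{MarkerGenotypeTable} with codes A/H/B
#' @export
extractMarkerGenotypes <- function(population, markerPositions = NULL,
                                   markerNames = NULL) {
  if (is.null(markerPositions))
    markerPositions <- population@map@markerPositions
  snp <- population@snpInfo
  markerPositions <- markerPositions[lengths(markerPositions) > 0]
  keys <- unlist(lapply(names(markerPositions), function(nm)
    paste0(nm, ":", markerPositions[[nm]])), use.names = FALSE)
  allKeys <- paste0(snp$chrom, ":", snp$pos)
  idx <- match(keys, allKeys)
  if (anyNA(idx))
    stop("unknown marker position(s): ",
         paste(keys[is.na(idx)], collapse = ", "))
  if (length(idx)) {
    info <- DataFrame(name = if (is.null(markerNames))
                        sprintf("M%02d", seq_along(idx)) else markerNames,
                      chrom = snp$chrom[idx], pos = snp$pos[idx])
    o <- order(info$chrom, info$pos)
    info <- info[o, ]; idx <- idx[o]
    g <- population@genotypes[, idx, drop = FALSE]
    codes <- matrix(c("A", "H", "B")[g + 1L], nrow = nrow(g),
                    dimnames = list(rownames(g), info$name))
  } else {
    info <- DataFrame(name = character(), chrom = character(),
                      pos = numeric())
    codes <- matrix(character(), nrow = nrow(population@genotypes), ncol = 0,
                    dimnames = list(rownames(population@genotypes), NULL))
  }
  new("MarkerGenotypeTable", genotypes = codes, markers = info,
      phenotype = population@phenotype)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.allCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Engineer a CDS pair carrying a frameshifting deletion
#'
#' Builds a random reference CDS (ATG start, terminal stop, no internal
#' in-frame stop) and a mutant copy carrying the configured deletion, then
#' rejection-samples the codons downstream of the deletion until the first
#' frameshifted stop codon truncates the mutant protein at exactly
#' \code{targetTruncatedAa} residues. Two protein domains are annotated,
#' one upstream and one downstream of the truncation point, so that effect
#' classification reports the downstream domain as lost.
#'
#' Defaults mirror a 13 bp deletion at CDS positions 502-514 truncating the
#' protein to 173 residues.
#'
#' @param totalLength reference CDS length in bp (multiple of 3)
#' @param deletionStart,deletionLength deletion coordinates (1-based bp)
#' @param targetTruncatedAa residues the truncated mutant protein must have;
#'   ignored for in-frame deletions
#' @param seed integer seed
#' @param maxIter rejection-sampling cap (default 10000)
#' @return list with \code{ref} and \code{mut} (\code{DNAString}) and
#'   \code{domains} (DFrame: name, start_aa, end_aa)
#' @export
makeCdsFixture <- function(totalLength = 1134, deletionStart = 502,
                           deletionLength = 13, targetTruncatedAa = 173,
                           seed = 1, maxIter = 10000) {
  stopifnot(totalLength %% 3 == 0,
            deletionStart >= 1,
            deletionStart + deletionLength - 1 <= totalLength)
  frameshift <- deletionLength %% 3 != 0
  nCodon <- totalLength / 3
  protLenRef <- nCodon - 1L
  if (frameshift) {
    stopifnot(targetTruncatedAa < totalLength / 3,
              3 * (targetTruncatedAa + 1) <= totalLength - deletionLength)
  }
  set.seed(as.integer(seed))
  codons <- .allCodons()
  nonstop <- setdiff(codons, .STOP_CODONS)
  makeRef <- function()
    paste0("ATG", paste(sample(nonstop, nCodon - 2L, replace = TRUE),
                        collapse = ""), sample(.STOP_CODONS, 1L))
  delEnd <- deletionStart + deletionLength - 1L
  for (it in seq_len(maxIter)) {
    ref <- makeRef()
    mut <- applyDeletion(ref, deletionStart, delEnd)
    if (!frameshift) break
    if (nchar(translateCds(mut)) == targetTruncatedAa) break
    if (it == maxIter)
      stop("could not engineer a ", targetTruncatedAa,
           "-residue truncation in ", maxIter, " iterations")
  }
  truncAt <- if (frameshift) targetTruncatedAa else protLenRef
  domains <- DataFrame(
    name = c("DIOX_N", "2OG-FeII_Oxy"),
    start_aa = c(30L, as.integer(truncAt + 20L)),
    end_aa = c(as.integer(floor(0.7 * truncAt)), as.integer(protLenRef - 10L)))
  list(ref = Biostrings::DNAString(ref), mut = Biostrings::DNAString(mut),
       domains = domains)
}

#' Simulate a qPCR Ct table for the Livak (2^-ddCt) estimator
#'
#' Ct values are generated so that [relativeExpression()] recovers the
#' configured fold changes exactly when \code{noiseSd = 0}:
#' reference-gene Ct is constant at \code{ctReference}, target-gene Ct is
#' \code{ctReference + baselineDeltaCt - log2(fold)}, and iid Gaussian
#' noise on the cycle scale is added to every well.
#'
#' @param foldChanges named numeric vector of true fold changes relative to
#'   the calibrator (one entry per sample)
#' @param calibrator sample id of the calibrator; appended with fold 1 if
#'   absent from \code{foldChanges}
#' @param ctReference reference-gene Ct level in cycles (default 20)
#' @param baselineDeltaCt calibrator's target-minus-reference Ct offset
#'   (default 5 cycles)
#' @param noiseSd Gaussian noise SD on Ct, in cycles
#' @param replicates biological replicates per sample x gene (default 3)
#' @param seed integer seed
#' @return data.frame with columns sample, gene, replicate, ct
#' @export
simulateCtTable <- function(foldChanges, calibrator, ctReference = 20,
                            baselineDeltaCt = 5, noiseSd = 0.2,
                            replicates = 3, seed = 1) {
  stopifnot(replicates >= 1, noiseSd >= 0, !is.null(names(foldChanges)))
  if (!calibrator %in% names(foldChanges))
    foldChanges <- c(foldChanges, setNames(1, calibrator))
  stopifnot(all(foldChanges > 0))
  set.seed(as.integer(seed))
  rows <- expand.grid(replicate = seq_len(replicates),
                      gene = c("target", "reference"),
                      sample = names(foldChanges),
                      stringsAsFactors = FALSE)
  mu <- ifelse(rows$gene == "reference", ctReference,
               ctReference + baselineDeltaCt -
                 log2(foldChanges[rows$sample]))
  data.frame(sample = rows$sample, gene = rows$gene,
             replicate = rows$replicate,
             ct = unname(mu + rnorm(nrow(rows), 0, noiseSd)))
}
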