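# Small simulation designs used across tests (built in code, never stored).

# one chromosome, dense SNPs, causal in the middle
tinyMap <- function(lengthBp = 1e6, lengthM = 1, spacing = 1e4) {
  geneticMap(
    data.frame(name = "chr1", length_bp = lengthBp, length_m = lengthM),
    list(chr1 = seq(spacing, lengthBp, by = spacing)))
}

tinyCausal <- function(map) {
  pos <- map@snpPositions$chr1
  pos[ceiling(length(pos) / 2)]
}

# a depth table with exact per-pool indices (fixed depth 10)
depthRow <- function(chrom, pos, iL, iS, depth = 10) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
             L_ref = round(depth * (1 - iL)), L_alt = round(depth * iL),
             S_ref = round(depth * (1 - iS)), S_alt = round(depth * iS))
}

# marker table built by hand from a code matrix (individuals x markers)
handTable <- function(codes, phenotype, pos = NULL, chrom = "chr1",
                      names = NULL) {
  if (is.null(names)) names <- sprintf("m%d", seq_len(ncol(codes)))
  if (is.null(pos)) pos <- seq_len(ncol(codes)) * 1e5
  info <- S4Vectors::DataFrame(name = names, chrom = chrom, pos = pos)
  dimnames(codes) <- list(sprintf("ind%03d", seq_len(nrow(codes))), names)
  new("MarkerGenotypeTable", genotypes = codes, markers = info,
      phenotype = phenotype)
}

# random valid SnpDepthTable
randomDepths <- function(n, seed) {
  set.seed(seed)
  snpDepthTable(data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(1e6, n), ref = "A", alt = "G",
    L_ref = rpois(n, 12), L_alt = rpois(n, 6),
    S_ref = rpois(n, 3), S_alt = rpois(n, 15)))
}

# random CDS: ATG + non-stop codons + terminal stop
randomCds <- function(nCodon, seed) {
  set.seed(seed)
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  nonstop <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(nonstop, nCodon - 2, replace = TRUE),
                      collapse = ""), "TAA")
}
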