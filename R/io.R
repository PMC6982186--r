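#' Read per-SNP bulk allele depths
#'
#' Two dialects are supported. The canonical TSV has the header
#' \code{chrom pos ref alt L_ref L_alt S_ref S_alt}. A VCF must contain
#' two samples named \code{L} and \code{S} with per-sample allele depths
#' (\code{AD}). Only biallelic single-base SNPs are kept; skipped rows are
#' counted in \code{metadata()$skipped}.
#'
#' @param path input file
#' @param format \code{"tsv"} (default) or \code{"vcf"}
#' @return a \linkS4class{SnpDepthTable}
#' @export
readSnpDepth <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") .readSnpDepthTsv(path) else .readSnpDepthVcf(path)
}

.readSnpDepthTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(.SNP_DEPTH_COLS, names(df))
  if (length(miss))
    stop("depth table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  bi <- nchar(df$ref) == 1L & nchar(df$alt) == 1L & df$ref != df$alt &
    !grepl(",", df$alt, fixed = TRUE)
  skipped <- sum(!bi)
  df <- df[bi, ]
  depths <- df[, c("pos", "L_ref", "L_alt", "S_ref", "S_alt")]
  bad <- which(!stats::complete.cases(depths) |
                 rowSums(as.matrix(depths) < 0) > 0)
  if (length(bad))
    stop("malformed depth row(s) at line(s): ",
         paste(head(bad + 1L, 10), collapse = ", "))
  out <- snpDepthTable(df)
  metadata(out)$skipped <- skipped
  out
}

.readSnpDepthVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samp <- colnames(v@gt)[-1]
  if (!all(c("L", "S") %in% samp))
    stop("VCF must contain samples named L and S; found: ",
         paste(samp, collapse = ", "))
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  bi <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) & !is.na(fix[, "ALT"])
  skipped <- sum(!bi)
  splitAd <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, "", 1L)),
         alt = as.integer(vapply(parts, `[`, "", 2L)))
  }
  adL <- splitAd(ad[, "L"]); adS <- splitAd(ad[, "S"])
  out <- snpDepthTable(data.frame(
    chrom = fix[bi, "CHROM"], pos = as.integer(fix[bi, "POS"]),
    ref = fix[bi, "REF"], alt = fix[bi, "ALT"],
    L_ref = adL$ref[bi], L_alt = adL$alt[bi],
    S_ref = adS$ref[bi], S_alt = adS$alt[bi]))
  metadata(out)$skipped <- skipped
  out
}

#' @rdname readSnpDepth
#' @param x a \linkS4class{SnpDepthTable}
#' @export
writeSnpDepth <- function(x, path) {
  stopifnot(is(x, "SnpDepthTable"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write marker genotype tables
#'
#' TSV dialect: first column \code{id}; one column per marker, headed
#' \code{name:chromosome:position}; final column \code{phenotype}
#' (long/short). Genotype codes A, H, B or \code{-} for missing.
#'
#' @param path file path
#' @return a \linkS4class{MarkerGenotypeTable}
#' @export
readMarkerTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "id" || names(df)[ncol(df)] != "phenotype")
    stop("marker table must start with 'id' and end with 'phenotype'")
  mcols <- names(df)[-c(1, ncol(df))]
  parts <- strsplit(mcols, ":", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("marker headers must be name:chromosome:position")
  info <- DataFrame(name = vapply(parts, `[`, "", 1L),
                    chrom = vapply(parts, `[`, "", 2L),
                    pos = as.numeric(vapply(parts, `[`, "", 3L)))
  g <- as.matrix(df[, mcols, drop = FALSE])
  g[g == "-"] <- NA
  o <- order(info$chrom, info$pos)
  g <- g[, o, drop = FALSE]
  info <- info[o, ]
  dimnames(g) <- list(df$id, info$name)
  new("MarkerGenotypeTable", genotypes = g, markers = info,
      phenotype = df$phenotype)
}

#' @rdname readMarkerTable
#' @param table a \linkS4class{MarkerGenotypeTable}
#' @export
writeMarkerTable <- function(table, path) {
  stopifnot(is(table, "MarkerGenotypeTable"))
  g <- table@genotypes
  g[is.na(g)] <- "-"
  info <- table@markers
  df <- data.frame(id = rownames(g), g, table@phenotype,
                   check.names = FALSE)
  names(df) <- c("id", paste(info$name, info$chrom, info$pos, sep = ":"),
                 "phenotype")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write qPCR Ct tables
#'
#' TSV with columns \code{sample, gene, replicate, ct}.
#'
#' @param path file path
#' @export
readCtTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname readCtTable
#' @param ct a Ct data.frame
#' @export
writeCtTable <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write candidate regions as BED
#'
#' Internal 1-based closed coordinates are converted to BED's 0-based
#' half-open convention (start - 1); the name field carries the peak delta
#' SNP index. A comment header documents the dialect.
#'
#' @param regions a \code{GRanges} from [callCandidateRegions()]
#' @param path output file
#' @export
writeRegionsBed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# candidate regions (BED: 0-based half-open); ",
                    "name = peak delta SNP index"), con)
  if (length(regions)) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(regions)),
      start = GenomicRanges::start(regions) - 1L,
      end = GenomicRanges::end(regions),
      name = format(regions$peak_delta, digits = 15, trim = TRUE,
                    scientific = FALSE))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeRegionsBed
#' @export
readRegionsBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(GenomicRanges::GRanges(seqnames = character(),
                                  IRanges::IRanges(),
                                  peak_delta = numeric()))
  df <- read.delim(text = lines, header = FALSE,
                   col.names = c("chrom", "start", "end", "name"))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end),
    peak_delta = as.numeric(df$name))
}

#' Write a window profile as TSV
#'
#' @param windows a \linkS4class{WindowProfile}
#' @param path output file
#' @export
writeWindowProfile <- function(windows, path) {
  stopifnot(is(windows, "WindowProfile"))
  write.table(as.data.frame(windows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Defaults reproduce the study design the package emulates: two 30-plant
#' bulks at ~30x depth, 1 Mb windows advancing 10 kb, 10,000 CI
#' replicates.
#'
#' @param seed integer master seed; all stage seeds derive from it
#' @param popSize F2 population size
#' @param bulkSize,meanDepth,depthModel bulk sequencing design
#' @param windowSize,step sliding-window geometry in bp
#' @param reps,levels null-CI simulation design
#' @param minTotalDepth,minIndex SNP filter thresholds
#' @param minConsecutive minimum significant-window run length
#' @param causalChrom,causalPos planted causal locus
#' @param deletionStart,deletionLength,targetTruncatedAa CDS fixture design
#' @return validated config list of class \code{bsamaprConfig}
#' @export
pipelineConfig <- function(seed = 1, popSize = 400, bulkSize = 30,
                           meanDepth = 30,
                           depthModel = "poisson", windowSize = 1e6,
                           step = 1e4, reps = 10000,
                           levels = c(0.95, 0.99), minTotalDepth = 7,
                           minIndex = 0.3, minConsecutive = 3,
                           causalChrom = "chr3", causalPos = 15e6,
                           deletionStart = 502, deletionLength = 13,
                           targetTruncatedAa = 173) {
  cfg <- list(seed = as.integer(seed), popSize = as.integer(popSize),
              bulkSize = as.integer(bulkSize), meanDepth = meanDepth,
              depthModel = depthModel, windowSize = windowSize, step = step,
              reps = as.integer(reps), levels = levels,
              minTotalDepth = minTotalDepth, minIndex = minIndex,
              minConsecutive = as.integer(minConsecutive),
              causalChrom = causalChrom, causalPos = causalPos,
              deletionStart = deletionStart,
              deletionLength = deletionLength,
              targetTruncatedAa = targetTruncatedAa)
  .validateConfig(cfg)
  class(cfg) <- "bsamaprConfig"
  cfg
}

.validateConfig <- function(cfg) {
  fail <- function(...) stop("invalid configuration: ", ...)
  if (cfg$popSize < 1) fail("popSize must be >= 1")
  if (cfg$bulkSize < 1) fail("bulkSize must be >= 1")
  if (cfg$meanDepth <= 0) fail("meanDepth must be > 0")
  if (cfg$reps < 100) fail("reps must be >= 100")
  if (cfg$step <= 0 || cfg$windowSize < cfg$step)
    fail("need windowSize >= step > 0")
  if (any(cfg$levels <= 0 | cfg$levels >= 1))
    fail("confidence levels must lie in (0, 1)")
  if (cfg$minConsecutive < 1) fail("minConsecutive must be >= 1")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; absent keys take the
#' defaults. Values are validated on load.
#'
#' @param path YAML file
#' @return a validated config list
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

# Polynomial rolling hash of the deparsed config, for provenance lines.
.configHash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}
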