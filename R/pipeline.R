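.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full mapping pipeline on synthetic data
#'
#' Simulates an F2 population and its bulk allele depths, tests phenotype
#' segregation, maps the trait by the delta SNP index with simulated null
#' confidence bounds, fine-maps with the marker ladder, classifies the
#' engineered coding deletion, and assembles a summary. Stage seeds are
#' derived deterministically from the master seed, so two runs with the
#' same configuration are identical (including written files).
#'
#' @param config a config list from [pipelineConfig()] or
#'   [readPipelineConfig()]
#' @param outputDir optional directory; when given, all stage outputs are
#'   written there (TSV/BED/FASTA plus a summary and provenance metadata)
#' @param map optional \linkS4class{GeneticMap}; default
#'   [defaultGeneticMap()] with the configured causal locus
#' @return list with elements \code{population, segregation, depths,
#'   filtered, windows, ci, regions, markers, interval, fixture, effect,
#'   summary}
#' @export
runPipeline <- function(config = pipelineConfig(), outputDir = NULL,
                        map = NULL) {
  .validateConfig(config)
  seed <- config$seed
  if (is.null(map))
    map <- .stage("map", defaultGeneticMap(causalChrom = config$causalChrom,
                                           causalPos = config$causalPos))
  pop <- .stage("simulate", simulateF2(map, config$causalChrom,
                                       config$causalPos, config$popSize,
                                       seed))
  counts <- .stage("segregation", {
    tab <- table(factor(phenotypes(pop), c("long", "short")))
    testStandardRatios(as.integer(tab))
  })
  depths <- .stage("bulk-depths",
    simulateBulkDepths(pop, config$bulkSize, config$meanDepth,
                       config$depthModel, seed = seed + 1L))
  filtered <- .stage("filter",
    filterSnps(depths, config$minTotalDepth, config$minIndex))
  chromLen <- setNames(map@chromosomes$length_bp, map@chromosomes$name)
  windows <- .stage("windows",
    windowProfiles(filtered, config$windowSize, config$step, chromLen))
  ci <- .stage("null-ci", {
    effd <- unique(pmax(1L, round(windows$eff_depth)))
    simulateNullCI(effd[!is.na(effd)], config$bulkSize, config$reps,
                   config$levels, seed = seed + 2L)
  })
  windows <- attachNullCI(windows, ci, max(config$levels[1], min(config$levels)))
  regions <- .stage("call-regions",
    callCandidateRegions(windows, minConsecutive = config$minConsecutive))
  markers <- .stage("marker-genotypes", extractMarkerGenotypes(pop))
  interval <- .stage("narrow-interval", narrowInterval(markers))
  fixture <- .stage("cds-fixture",
    makeCdsFixture(deletionStart = config$deletionStart,
                   deletionLength = config$deletionLength,
                   targetTruncatedAa = config$targetTruncatedAa,
                   seed = seed + 3L))
  effect <- .stage("classify-effect",
    classifyEffect(fixture$ref, fixture$mut, config$deletionStart,
                   config$deletionStart + config$deletionLength - 1,
                   fixture$domains))
  onCausal <- as.character(GenomicRanges::seqnames(regions)) ==
    config$causalChrom &
    GenomicRanges::start(regions) <= config$causalPos &
    GenomicRanges::end(regions) >= config$causalPos
  summary <- list(
    seed = seed, config_hash = .configHash(config),
    phenotype_counts = as.integer(table(factor(phenotypes(pop),
                                               c("long", "short")))),
    best_ratio = counts$best,
    n_snps_input = nrow(depths), n_snps_kept = nrow(filtered),
    n_windows = nrow(windows), n_regions = length(regions),
    causal_chrom = config$causalChrom, causal_pos = config$causalPos,
    causal_recovered = any(onCausal),
    interval = c(start = interval@start, end = interval@end,
                 length = interval@length),
    frameshift = effect@frameshift,
    protein_length_mut = effect@proteinLengthMut,
    lost_domains = as.character(effect@lostDomains$name))
  result <- list(population = pop, segregation = counts, depths = depths,
                 filtered = filtered, windows = windows, ci = ci,
                 regions = regions, markers = markers, interval = interval,
                 fixture = fixture, effect = effect, summary = summary)
  if (!is.null(outputDir)) .writePipelineOutputs(result, config, outputDir)
  result
}

.writePipelineOutputs <- function(result, config, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outputDir, f)
  writeSnpDepth(result$depths, p("snp_depths.tsv"))
  writeWindowProfile(result$windows, p("windows.tsv"))
  writeRegionsBed(result$regions, p("regions.bed"))
  writeMarkerTable(result$markers, p("markers.tsv"))
  seqs <- Biostrings::DNAStringSet(list(reference = result$fixture$ref,
                                        mutant = result$fixture$mut))
  Biostrings::writeXStringSet(seqs, p("cds.fasta"))
  s <- result$summary
  lines <- c(
    sprintf("seed\t%d", s$seed),
    sprintf("config_hash\t%s", s$config_hash),
    sprintf("phenotypes_long_short\t%d,%d", s$phenotype_counts[1],
            s$phenotype_counts[2]),
    sprintf("best_segregation_ratio\t%s", s$best_ratio),
    sprintf("snps_input\t%d", s$n_snps_input),
    sprintf("snps_kept\t%d", s$n_snps_kept),
    sprintf("windows\t%d", s$n_windows),
    sprintf("candidate_regions\t%d", s$n_regions),
    sprintf("causal_recovered\t%s", s$causal_recovered),
    sprintf("interval\t%s:%s-%s (%s bp)", config$causalChrom,
            format(s$interval[["start"]], scientific = FALSE),
            format(s$interval[["end"]], scientific = FALSE),
            format(s$interval[["length"]], scientific = FALSE)),
    sprintf("frameshift\t%s", s$frameshift),
    sprintf("truncated_protein_aa\t%d", s$protein_length_mut),
    sprintf("lost_domains\t%s", paste(s$lost_domains, collapse = ",")))
  writeLines(lines, p("summary.tsv"))
  meta <- c(list(config_hash = s$config_hash), unclass(config))
  yaml::write_yaml(meta, p("metadata.yaml"))
  invisible(outputDir)
}
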