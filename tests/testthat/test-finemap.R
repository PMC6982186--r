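test_that("in-silico digestion cuts at every site occurrence", {
  set.seed(11)
  b <- c("A", "C", "G", "T")
  # 100 bp amplicon, one EcoRI site starting at base 41 (cut after 41)
  flank1 <- paste(sample(b, 40, replace = TRUE), collapse = "")
  flank2 <- paste(sample(b, 54, replace = TRUE), collapse = "")
  amp <- gsub("GAATTC", "GAATCC", paste0(flank1, "GAATTC", flank2))
  amp <- paste0(substr(amp, 1, 40), "GAATTC", substr(amp, 47, 100))
  frags <- capsDigest(amp, "GAATTC", 1)
  expect_identical(frags, c(41L, 59L))

  # no site: one full-length fragment
  expect_identical(capsDigest("ACGTACGTAC", "GGGG", 1), 10L)

  # overlapping occurrences all cut (sites at 1..4, cut after each base)
  expect_identical(capsDigest("AAAAA", "AA", 1), rep(1L, 5))

  expect_error(capsDigest("ACGN", "AC", 1), "A/C/G/T")
  expect_error(capsDigest("ACGT", "ACGTT", 1), "shorter")
})

test_that("fragment lengths conserve amplicon length on random sequences", {
  set.seed(12)
  b <- c("A", "C", "G", "T")
  for (i in 1:20) {
    n <- sample(50:300, 1)
    amp <- paste(sample(b, n, replace = TRUE), collapse = "")
    site <- paste(sample(b, sample(4:6, 1), replace = TRUE), collapse = "")
    off <- sample(0:nchar(site), 1)
    expect_identical(sum(capsDigest(amp, site, off)), n)
  }
})

test_that("CAPS polymorphism detection equals multiset comparison", {
  # SNP destroys the only site in one parent
  a <- "AAAAGAATTCAAAAAAAAAA"
  bseq <- "AAAAGAATCCAAAAAAAAAA"
  r <- capsPolymorphic(a, bseq, "GAATTC", 1)
  expect_true(r$polymorphic)
  expect_identical(length(r$fragmentsA), 2L)
  expect_identical(length(r$fragmentsB), 1L)
  expect_false(capsPolymorphic(a, a, "GAATTC", 1)$polymorphic)

  set.seed(13)
  bases <- c("A", "C", "G", "T")
  for (i in 1:15) {
    s1 <- paste(sample(bases, 120, replace = TRUE), collapse = "")
    s2 <- paste(sample(bases, 120, replace = TRUE), collapse = "")
    site <- paste(sample(bases, 4, replace = TRUE), collapse = "")
    got <- capsPolymorphic(s1, s2, site, 2)
    expect_identical(got$polymorphic,
                     !identical(sort(capsDigest(s1, site, 2)),
                                sort(capsDigest(s2, site, 2))))
  }
})

test_that("recombinant listing is exact and symmetric", {
  codes <- matrix(c("A", "A",
                    "H", "H",
                    "B", "H",   # discordant
                    "A", "H",   # discordant
                    "B", "A",   # discordant
                    NA,  "B",   # excluded: missing
                    "H", "H"), ncol = 2, byrow = TRUE)
  phen <- c("long", "long", "short", "long", "long", "short", "long")
  tab <- handTable(codes, phen)
  got <- findRecombinants(tab, "m1", "m2")
  expect_identical(got, c("ind003", "ind004", "ind005"))
  expect_identical(findRecombinants(tab, "m2", "m1"), got)
  expect_error(findRecombinants(tab, "m1", "nope"), "unknown marker")

  # all identical at both markers: empty
  same <- handTable(matrix("H", 5, 2), rep("long", 5))
  expect_identical(length(findRecombinants(same, "m1", "m2")), 0L)
})

test_that("interval narrowing reproduces the flanking-marker arithmetic", {
  # 135 individuals, markers CAPS90 / gene-internal indel / CAPS91;
  # 12 recombinants contradict the outer markers, none the middle one
  n <- 135
  codes <- matrix(rep(c("A", "A", "A"), n), ncol = 3, byrow = TRUE)
  phen <- rep("long", n)
  short <- 1:35
  codes[short, ] <- "B"; phen[short] <- "short"
  het <- 36:102
  codes[het, ] <- "H"
  # 6 recombinants at each outer marker (phenotype short, non-B outside)
  codes[1:6, 1] <- "H"
  codes[7:12, 3] <- "H"
  tab <- handTable(codes, phen, pos = c(1850884, 1855000, 1859409),
                   chrom = "chr9", names = c("CAPS90", "indel13", "CAPS91"))
  res <- narrowInterval(tab)
  expect_identical(flankingMarkers(res),
                   c(left = "CAPS90", right = "CAPS91"))
  expect_identical(res@start, 1850884)
  expect_identical(res@end, 1859409)
  expect_identical(intervalLength(res), 8525)      # 8.525 kb
  expect_identical(res@nRecombinants, 12L)
})

test_that("no recombination information spans the outermost markers", {
  codes <- matrix(rep(c("A", "A", "A", "A"), 10), ncol = 4, byrow = TRUE)
  codes[1:3, ] <- "B"
  phen <- c(rep("short", 3), rep("long", 7))
  tab <- handTable(codes, phen)
  res <- narrowInterval(tab)
  expect_identical(flankingMarkers(res), c(left = "m1", right = "m4"))
})

test_that("a causal locus between two markers is still localized", {
  # recombinants on both sides of the gap: no marker fully consistent
  codes <- matrix(rep(c("A", "A"), 20), ncol = 2, byrow = TRUE)
  phen <- rep("long", 20)
  codes[1:5, ] <- "B"; phen[1:5] <- "short"
  codes[1, 1] <- "H"        # recombinant left of the causal locus
  codes[2, 2] <- "H"        # recombinant right of it
  tab <- handTable(codes, phen)
  res <- narrowInterval(tab)
  expect_identical(flankingMarkers(res), c(left = "m1", right = "m2"))
  expect_identical(res@nRecombinants, 2L)
})

test_that("an unlinked marker set is rejected", {
  set.seed(14)
  codes <- matrix(sample(c("A", "H", "B"), 60, replace = TRUE), ncol = 2)
  phen <- sample(c("long", "short"), 30, replace = TRUE)
  # force overlap of violator sets at the only adjacent pair
  codes[phen == "short", ] <- "A"
  expect_error(narrowInterval(handTable(codes, phen)), "not linked")
  expect_error(narrowInterval(handTable(codes[, 1, drop = FALSE], phen)),
               "two markers")
})

test_that("simulated populations localize the causal locus", {
  # ladder of 7 markers, causal strictly between m4 and m5 (2 cM gaps)
  map <- geneticMap(
    data.frame(name = "chr1", length_bp = 1.4e6, length_m = 1.4),
    list(chr1 = c(seq(2e5, 8e5, 2e5), 8.5e5, seq(9e5, 1.3e6, 2e5))))
  markers <- list(chr1 = c(seq(2e5, 8e5, 2e5), seq(9e5, 1.3e6, 2e5)))
  hits <- 0
  nSeeds <- 40
  for (s in seq_len(nSeeds)) {
    pop <- simulateF2(map, "chr1", 8.5e5, n = 200, seed = 3000 + s)
    tab <- extractMarkerGenotypes(pop, markers)
    res <- tryCatch(narrowInterval(tab), error = function(e) NULL)
    if (!is.null(res) && res@start <= 8.5e5 && res@end >= 8.5e5)
      hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.95 * nSeeds))
})

test_that("interval length shrinks weakly as marker density grows", {
  map <- tinyMap(lengthBp = 1e6, lengthM = 1, spacing = 5e4)
  causal <- tinyCausal(map)
  pop <- simulateF2(map, "chr1", causal, n = 300, seed = 71)
  dense <- map@snpPositions$chr1
  sparse <- dense[seq(1, length(dense), by = 4)]
  sparse <- sort(unique(c(sparse, causal)))
  lenFor <- function(pos) {
    intervalLength(narrowInterval(
      extractMarkerGenotypes(pop, list(chr1 = pos))))
  }
  expect_lte(lenFor(dense), lenFor(sparse))
})

test_that("co-segregation summary counts classes and concordance", {
  n <- 135
  codes <- matrix(c(rep("A", 33), rep("H", 67), rep("B", 35)), ncol = 1)
  phen <- c(rep("long", 100), rep("short", 35))
  tab <- handTable(codes, phen)
  s <- cosegregationSummary(tab, "m1")
  expect_identical(unname(s$counts), c(33L, 67L, 35L))
  expect_identical(s$concordance, 1)
  expect_identical(s$segregation@df, 2L)
  exp <- n * c(1, 2, 1) / 4
  expect_equal(chi2(s$segregation), sum((c(33, 67, 35) - exp)^2 / exp))

  # one discordant individual out of 135
  phen2 <- phen; phen2[1] <- "short"
  s2 <- cosegregationSummary(handTable(codes, phen2), "m1")
  expect_equal(s2$concordance, 134 / 135)
})
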