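test_that("snpIndex follows the all-reads-from-reference convention", {
  expect_identical(snpIndex(30, 0), 0)
  expect_identical(snpIndex(0, 30), 1)
  expect_identical(snpIndex(15, 15), 0.5)
  expect_true(is.na(snpIndex(0, 0)))
  expect_equal(snpIndex(c(30, 0, 0), c(0, 30, 0)), c(0, 1, NA))
})

test_that("SNP filter applies depth and index rules and logs removals", {
  x <- snpDepthTable(rbind(
    depthRow("c", 100, 0.5, 1.0),                    # passes both
    data.frame(chrom = "c", pos = 200, ref = "A", alt = "T",
               L_ref = 10, L_alt = 5, S_ref = 4, S_alt = 1),  # S depth 5
    depthRow("c", 300, 0.1, 0.2)))                   # low index
  f <- filterSnps(x, minTotalDepth = 7, minIndex = 0.3)
  expect_identical(nrow(f), 1L)
  expect_identical(f$pos, 100L)
  log <- S4Vectors::metadata(f)$filter
  expect_identical(log$removed_depth, 1L)
  expect_identical(log$removed_index, 1L)

  # zero thresholds are the identity
  f0 <- filterSnps(x, 0, 0)
  expect_identical(as.data.frame(f0), as.data.frame(x))
})

test_that("filter survivors equal a brute-force per-record evaluation", {
  x <- randomDepths(100, seed = 77)
  f <- filterSnps(x, minTotalDepth = 7, minIndex = 0.3)
  keep <- vapply(seq_len(nrow(x)), function(i) {
    tl <- x$L_ref[i] + x$L_alt[i]; ts <- x$S_ref[i] + x$S_alt[i]
    if (tl < 7 || ts < 7) return(FALSE)
    idx <- c(if (tl > 0) x$L_alt[i] / tl, if (ts > 0) x$S_alt[i] / ts)
    max(idx) >= 0.3
  }, TRUE)
  expect_identical(nrow(f), sum(keep))
  expect_identical(f$pos, x$pos[keep])
})

test_that("window means average member SNP indices", {
  x <- snpDepthTable(rbind(depthRow("c", 5000, 0.2, 0.5),
                           depthRow("c", 15000, 0.4, 0.5)))
  w <- windowProfiles(x, windowSize = 2e4, step = 1e4,
                      chromLengths = c(c = 2e4))
  expect_identical(nrow(w), 1L)
  expect_equal(w$index_L, 0.3)
  expect_equal(w$delta, 0.3 - 0.5)
  expect_identical(w$n_snps, 2L)

  # a single-SNP window reports that SNP's index
  x1 <- snpDepthTable(depthRow("c", 5000, 0.7, 0.1))
  w1 <- windowProfiles(x1, windowSize = 1e4, step = 1e4,
                       chromLengths = c(c = 1e4))
  expect_equal(w1$index_L, 0.7)
  expect_equal(w1$index_S, 0.1)
})

test_that("window tiling covers the chromosome at the configured step", {
  x <- snpDepthTable(depthRow("c", 999999, 0.5, 0.5))
  w <- windowProfiles(x, windowSize = 1e6, step = 1e4,
                      chromLengths = c(c = 2e6))
  expect_identical(nrow(w), 101L)        # floor((2e6-1e6)/1e4) + 1
  expect_true(all(w$start <= 2e6 - 1e6 + 1))
  expect_identical(w$start[1], 1)
  expect_true(all(diff(w$start) == 1e4))
  # empty windows carry missing values
  expect_true(any(w$n_snps == 0))
  expect_true(all(is.na(w$delta[w$n_snps == 0])))
})

test_that("window means equal an independent grouping pass on random data", {
  x <- randomDepths(300, seed = 13)
  W <- 2e5; S <- 5e4
  lens <- c(chr1 = 1e6, chr2 = 1e6)
  w <- windowProfiles(x, W, S, lens)
  iL <- snpIndex(x$L_ref, x$L_alt)
  for (k in sample(nrow(w), min(nrow(w), 40))) {
    inWin <- x$chrom == w$chrom[k] & x$pos >= w$start[k] &
      x$pos < w$start[k] + W
    vals <- iL[inWin & !is.na(iL)]
    if (length(vals)) expect_equal(w$index_L[k], mean(vals))
    else expect_true(is.na(w$index_L[k]))
    expect_identical(w$n_snps[k], sum(inWin))
  }
  # bounded statistics everywhere
  expect_true(all(w$index_L >= 0 & w$index_L <= 1, na.rm = TRUE))
  expect_true(all(abs(w$delta) <= 1, na.rm = TRUE))
})

test_that("null CI bounds shrink with depth and vanish in the limit", {
  ci <- simulateNullCI(c(10, 100), bulkSize = 30, reps = 10000, seed = 55)
  t10 <- ci[ci$depth == 10 & ci$level == 0.95, ]
  t100 <- ci[ci$depth == 100 & ci$level == 0.95, ]
  expect_lt(t10$lower, t100$lower)
  expect_gt(t10$upper, t100$upper)
  # high depth and huge bulks: both bounds collapse toward 0
  big <- simulateNullCI(5000, bulkSize = 5000, reps = 2000, seed = 56)
  expect_lt(max(abs(c(big$lower, big$upper))), 0.05)
  # bounds bracket zero and 99% is wider than 95%
  expect_true(all(ci$lower <= 0 & ci$upper >= 0))
  w95 <- t10$upper - t10$lower
  t10_99 <- ci[ci$depth == 10 & ci$level == 0.99, ]
  expect_gt(t10_99$upper - t10_99$lower, w95)
})

test_that("null CI bounds match a brute-force oracle with another generator", {
  ci <- simulateNullCI(30, bulkSize = 30, reps = 200000, seed = 57)
  # oracle: individuals sampled explicitly, reads by multinomial
  set.seed(91)
  reps <- 200000
  oneDelta <- function() {
    idx <- function() {
      g <- sample(0:2, 30, replace = TRUE, prob = c(1, 2, 1) / 4)
      f <- sum(g) / 60
      counts <- rmultinom(1, 30, c(1 - f, f))
      counts[2] / 30
    }
    idx() - idx()
  }
  deltas <- replicate(reps, oneDelta())
  q <- quantile(deltas, c(0.025, 0.975), names = FALSE)
  t95 <- ci[ci$level == 0.95, ]
  expect_lt(abs(t95$lower - q[1]), 0.02)
  expect_lt(abs(t95$upper - q[2]), 0.02)
})

test_that("attachNullCI looks up the nearest simulated depth", {
  x <- snpDepthTable(rbind(depthRow("c", 5000, 0.5, 0.5, depth = 10),
                           depthRow("c", 255000, 0.5, 0.5, depth = 100)))
  w <- windowProfiles(x, windowSize = 1e4, step = 1e4,
                      chromLengths = c(c = 26e4))
  ci <- simulateNullCI(c(10, 100), reps = 5000, seed = 3)
  w2 <- attachNullCI(w, ci, level = 0.95)
  t <- as.data.frame(ci[ci$level == 0.95, ])
  expect_equal(w2$ci_lower[w2$n_snps > 0 & w2$start == 1],
               t$lower[t$depth == 10])
  expect_equal(w2$ci_lower[w2$n_snps > 0 & w2$start == 250001],
               t$lower[t$depth == 100])
  expect_error(attachNullCI(w, ci, level = 0.5), "level")
})

test_that("no regions are called when all deltas are null", {
  x <- snpDepthTable(do.call(rbind, lapply(seq(1e4, 5e5, 1e4), function(p)
    depthRow("c", p, 0.5, 0.5, depth = 30))))
  w <- windowProfiles(x, windowSize = 5e4, step = 1e4,
                      chromLengths = c(c = 5e5))
  ci <- simulateNullCI(30, reps = 2000, seed = 8)
  regions <- callCandidateRegions(w, ci)
  expect_identical(length(regions), 0L)
})

test_that("a planted causal locus is recovered with the expected delta sign", {
  map <- defaultGeneticMap()
  cfg <- pipelineConfig(seed = 201, reps = 2000)
  pop <- simulateF2(map, "chr3", 15e6, n = 400, seed = 201)
  d <- simulateBulkDepths(pop, 30, 30, "poisson", seed = 202)
  f <- filterSnps(d)
  lens <- setNames(map@chromosomes$length_bp, map@chromosomes$name)
  w <- windowProfiles(f, 1e6, 1e4, lens)
  ci <- simulateNullCI(unique(pmax(1, round(w$eff_depth[!is.na(w$eff_depth)]))),
                       30, reps = 2000, seed = 203)
  regions <- callCandidateRegions(w, ci, minConsecutive = 3)
  hit <- as.character(GenomicRanges::seqnames(regions)) == "chr3" &
    GenomicRanges::start(regions) <= 15e6 & GenomicRanges::end(regions) >= 15e6
  expect_true(any(hit))
  expect_lt(regions$peak_delta[which(hit)[1]], 0)  # L - S at a recessive locus

  # window over the causal SNP sits near the Mendelian expectation -2/3
  onCausal <- w$chrom == "chr3" & w$start <= 15e6 & w$start + 1e6 > 15e6
  centreDist <- abs(w$start[onCausal] + 5e5 - 15e6)
  causalDelta <- w$delta[onCausal][which.min(centreDist)]
  expect_lt(abs(causalDelta - (-2 / 3)), 0.2)

  # far from the causal locus (unlinked chromosome) the mean delta is ~0
  # ~30 non-overlapping 1 Mb blocks on a 30 Mb chromosome
  off <- w$chrom == "chr1" & !is.na(w$delta)
  expect_lt(abs(mean(w$delta[off])), 3 * sd(w$delta[off]) / sqrt(30))
})
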