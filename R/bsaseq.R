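#' SNP index: fraction of reads carrying the alternate allele
#'
#' By the polarization convention (reference = long parent), an index of 0
#' means every read matched the reference genome. Zero total depth yields
#' \code{NA}; such records are excluded from window means.
#'
#' @param refDepth,altDepth read counts (vectorized)
#' @return numeric in [0, 1], or NA where total depth is zero
#' @examples
#' snpIndex(30, 0)   # 0
#' snpIndex(15, 15)  # 0.5
#' @export
snpIndex <- function(refDepth, altDepth) {
  stopifnot(all(refDepth >= 0, na.rm = TRUE),
            all(altDepth >= 0, na.rm = TRUE))
  total <- refDepth + altDepth
  ifelse(total > 0, altDepth / total, NA_real_)
}

#' Filter SNP records on per-pool depth and minimum index
#'
#' Retains records whose total depth in \emph{both} pools reaches
#' \code{minTotalDepth} and whose larger per-pool SNP index reaches
#' \code{minIndex} (drops SNPs where neither bulk shows the alternate
#' allele appreciably, typically reference-genome artefacts). Counts
#' removed per rule are stored in \code{metadata(x)$filter}.
#'
#' @param x a \linkS4class{SnpDepthTable}
#' @param minTotalDepth minimum per-pool total depth (default 7)
#' @param minIndex minimum of max(index_L, index_S) (default 0.3)
#' @return filtered \linkS4class{SnpDepthTable}
#' @export
filterSnps <- function(x, minTotalDepth = 7, minIndex = 0.3) {
  stopifnot(is(x, "SnpDepthTable"), minTotalDepth >= 0, minIndex >= 0)
  totL <- x$L_ref + x$L_alt
  totS <- x$S_ref + x$S_alt
  okDepth <- totL >= minTotalDepth & totS >= minTotalDepth
  iL <- snpIndex(x$L_ref, x$L_alt)
  iS <- snpIndex(x$S_ref, x$S_alt)
  maxI <- pmax(ifelse(is.na(iL), -Inf, iL), ifelse(is.na(iS), -Inf, iS))
  okIndex <- if (minIndex <= 0) rep(TRUE, nrow(x)) else maxI >= minIndex
  keep <- okDepth & okIndex
  out <- x[keep, ]
  metadata(out)$filter <- list(
    input = nrow(x),
    removed_depth = sum(!okDepth),
    removed_index = sum(okDepth & !okIndex),
    kept = sum(keep),
    min_total_depth = minTotalDepth, min_index = minIndex)
  out
}

#' Sliding-window SNP-index profile
#'
#' Windows of \code{windowSize} bp advance by \code{step} bp, anchored at
#' position 1 and spanning \code{[start, start + windowSize)} (half-open).
#' The per-pool window statistic is the unweighted mean of member SNP
#' indices (optionally depth-weighted); the delta SNP index is the L-pool
#' mean minus the S-pool mean. SNPs with zero depth in a pool contribute
#' nothing to that pool's mean. Windows without SNPs carry NA.
#'
#' @param x a \linkS4class{SnpDepthTable} (sorted internally)
#' @param windowSize window width in bp (default 1 Mb)
#' @param step window increment in bp (default 10 kb)
#' @param chromLengths named vector of chromosome lengths; defaults to the
#'   last SNP position per chromosome
#' @param weighted if TRUE, weight each SNP's index by its total depth
#' @return a \linkS4class{WindowProfile} (CI columns NA until
#'   [attachNullCI()])
#' @export
windowProfiles <- function(x, windowSize = 1e6, step = 1e4,
                           chromLengths = NULL, weighted = FALSE) {
  stopifnot(is(x, "SnpDepthTable"), windowSize >= step, step > 0)
  x <- x[order(x$chrom, x$pos), ]
  if (is.null(chromLengths)) {
    chromLengths <- vapply(split(x$pos, x$chrom), max, 0)
  }
  iL <- snpIndex(x$L_ref, x$L_alt)
  iS <- snpIndex(x$S_ref, x$S_alt)
  depth <- ((x$L_ref + x$L_alt) + (x$S_ref + x$S_alt)) / 2
  pieces <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    starts <- seq(1, max(len - windowSize + 1, 1), by = step)
    win <- IRanges::IRanges(start = starts, width = windowSize)
    sel <- which(x$chrom == chr)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(x$pos[sel], width = 1L), win)
    wi <- S4Vectors::subjectHits(hits)
    si <- sel[S4Vectors::queryHits(hits)]
    wmean <- function(v, w) {
      num <- tapply(ifelse(is.na(v), 0, v * w), wi, sum)
      den <- tapply(ifelse(is.na(v), 0, w), wi, sum)
      ifelse(den > 0, num / den, NA_real_)
    }
    wts <- if (weighted) depth[si] else rep(1, length(si))
    mL <- wmean(iL[si], wts)
    mS <- wmean(iS[si], wts)
    mD <- wmean(depth[si], rep(1, length(si)))
    n <- tabulate(wi, nbins = length(starts))
    grp <- as.integer(names(mL))
    indexL <- indexS <- effd <- rep(NA_real_, length(starts))
    indexL[grp] <- mL; indexS[grp] <- mS; effd[grp] <- mD
    DataFrame(chrom = chr, start = starts,
              end = pmin(starts + windowSize - 1, len),
              n_snps = n, index_L = indexL, index_S = indexS,
              delta = indexL - indexS, eff_depth = effd,
              ci_lower = NA_real_, ci_upper = NA_real_)
  })
  new("WindowProfile", do.call(rbind, pieces),
      windowSize = windowSize, step = step)
}

#' Simulate null confidence bounds for the delta SNP index
#'
#' Under the no-locus null, each pool's short-parent allele count is drawn
#' Binomial(2 x bulkSize, 1/2) (random F2 bulk composition), then the
#' alternate-read count Binomial(depth, k / (2 x bulkSize)). The delta SNP
#' index replicate is the difference of the two pools' indices; bounds are
#' the empirical \eqn{(1-conf)/2} and \eqn{1-(1-conf)/2} quantiles per
#' depth.
#'
#' @param readDepths integer read depths to tabulate (per pool)
#' @param bulkSize individuals per bulk (default 30)
#' @param reps replicates per depth (default 10000, minimum 100)
#' @param levels confidence levels (default 0.95 and 0.99)
#' @param seed integer seed
#' @return a \linkS4class{NullCiTable}
#' @export
simulateNullCI <- function(readDepths, bulkSize = 30, reps = 10000,
                           levels = c(0.95, 0.99), seed) {
  stopifnot(reps >= 100, bulkSize >= 1, all(readDepths >= 1))
  readDepths <- sort(unique(as.integer(readDepths)))
  set.seed(as.integer(seed))
  rows <- lapply(readDepths, function(d) {
    kL <- rbinom(reps, 2 * bulkSize, 0.5)
    kS <- rbinom(reps, 2 * bulkSize, 0.5)
    dlt <- rbinom(reps, d, kL / (2 * bulkSize)) / d -
           rbinom(reps, d, kS / (2 * bulkSize)) / d
    qs <- quantile(dlt, c((1 - levels) / 2, 1 - (1 - levels) / 2),
                   names = FALSE)
    DataFrame(depth = d, level = levels,
              lower = qs[seq_along(levels)],
              upper = qs[length(levels) + seq_along(levels)])
  })
  new("NullCiTable", do.call(rbind, rows), reps = as.integer(reps),
      bulkSize = as.integer(bulkSize), seed = as.integer(seed))
}

#' Attach null confidence bounds to a window profile
#'
#' Each window's effective depth (mean per-SNP total depth across both
#' pools, rounded) is matched to the nearest tabulated depth.
#'
#' @param windows a \linkS4class{WindowProfile}
#' @param ci a \linkS4class{NullCiTable}
#' @param level confidence level present in \code{ci} (default 0.95)
#' @return the profile with \code{ci_lower}/\code{ci_upper} filled in
#' @export
attachNullCI <- function(windows, ci, level = 0.95) {
  stopifnot(is(windows, "WindowProfile"), is(ci, "NullCiTable"))
  tab <- ci[abs(ci$level - level) < 1e-9, ]
  if (!nrow(tab)) stop("confidence level ", level, " not in the CI table")
  effd <- round(windows$eff_depth)
  near <- vapply(effd, function(d) {
    if (is.na(d)) NA_integer_ else which.min(abs(tab$depth - d))
  }, 1L)
  df <- as(windows, "DFrame")
  df$ci_lower <- tab$lower[near]
  df$ci_upper <- tab$upper[near]
  new("WindowProfile", df, windowSize = windows@windowSize,
      step = windows@step)
}

#' Call candidate regions from a window profile
#'
#' Windows whose delta SNP index falls outside the null bounds, with a
#' consistent sign across at least \code{minConsecutive} consecutive
#' windows (same chromosome, starts \code{step} apart), are merged into
#' maximal runs. Each region reports the window of extreme |delta| as its
#' peak.
#'
#' @param windows a \linkS4class{WindowProfile}
#' @param ci optional \linkS4class{NullCiTable}; required unless bounds are
#'   already attached
#' @param minConsecutive minimum run length (default 3)
#' @param level confidence level (default 0.95)
#' @return a \code{GRanges} of candidate regions with metadata columns
#'   \code{peak_delta}, \code{peak_start}, \code{n_windows}
#' @export
callCandidateRegions <- function(windows, ci = NULL, minConsecutive = 3,
                                 level = 0.95) {
  stopifnot(is(windows, "WindowProfile"), minConsecutive >= 1)
  if (!is.null(ci)) windows <- attachNullCI(windows, ci, level)
  if (!nrow(windows) || all(is.na(windows$ci_lower) & is.na(windows$ci_upper)))
    if (is.null(ci)) stop("no CI bounds attached; supply `ci`")
  empty <- GenomicRanges::GRanges(
    seqnames = character(), IRanges::IRanges(),
    peak_delta = numeric(), peak_start = numeric(), n_windows = integer())
  if (!nrow(windows)) return(empty)
  sig <- !is.na(windows$delta) &
    (windows$delta < windows$ci_lower | windows$delta > windows$ci_upper)
  if (!any(sig)) return(empty)
  sgn <- sign(windows$delta)
  idx <- which(sig)
  newRun <- c(TRUE, diff(idx) != 1L |
                windows$chrom[idx[-1]] != windows$chrom[idx[-length(idx)]] |
                windows$start[idx[-1]] - windows$start[idx[-length(idx)]] !=
                  windows@step |
                sgn[idx[-1]] != sgn[idx[-length(idx)]])
  runId <- cumsum(newRun)
  rows <- lapply(split(idx, runId), function(ii) {
    if (length(ii) < minConsecutive) return(NULL)
    peak <- ii[which.max(abs(windows$delta[ii]))]
    data.frame(chrom = windows$chrom[ii[1]],
               start = windows$start[ii[1]],
               end = windows$end[ii[length(ii)]],
               peak_delta = windows$delta[peak],
               peak_start = windows$start[peak],
               n_windows = length(ii))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows) || !nrow(rows)) return(empty)
  GenomicRanges::GRanges(
    seqnames = rows$chrom,
    IRanges::IRanges(start = rows$start, end = rows$end),
    peak_delta = rows$peak_delta, peak_start = rows$peak_start,
    n_windows = rows$n_windows)
}
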