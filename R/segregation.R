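#' Chi-square goodness of fit against a segregation ratio
#'
#' Pearson statistic \eqn{\sum (O-E)^2/E} with expected counts
#' \eqn{E_i = N w_i / \sum w}, no continuity correction, and an upper-tail
#' p-value on \code{length(observed) - 1} degrees of freedom.
#'
#' @param observed non-negative integer class counts (>= 2 classes)
#' @param expectedRatio positive ratio weights, e.g. \code{c(3, 1)}
#' @return a \linkS4class{SegregationResult}
#' @examples
#' chiSquareGof(c(278, 89), c(3, 1))   # chi2 ~ 0.110, p ~ 0.740
#' chiSquareGof(c(38, 42), c(1, 1))    # chi2 = 0.200, p ~ 0.6547
#' @export
chiSquareGof <- function(observed, expectedRatio) {
  if (length(observed) < 2)
    stop("at least two phenotype/genotype classes are required")
  if (length(observed) != length(expectedRatio))
    stop("observed and expectedRatio must have equal length")
  if (any(observed < 0) || anyNA(observed))
    stop("observed counts must be non-negative")
  if (any(expectedRatio <= 0) || anyNA(expectedRatio))
    stop("ratio weights must be positive")
  total <- sum(observed)
  if (total <= 0) stop("total count must be positive")
  expected <- total * expectedRatio / sum(expectedRatio)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  new("SegregationResult", observed = as.integer(observed),
      expectedRatio = as.numeric(expectedRatio), chi2 = stat, df = df,
      p = pchisq(stat, df, lower.tail = FALSE))
}

.STANDARD_RATIOS <- list(
  "3:1" = c(3, 1), "1:1" = c(1, 1), "1:2:1" = c(1, 2, 1))

#' Test observed counts against the standard Mendelian ratios
#'
#' Fits every standard ratio compatible with the number of classes
#' (3:1 and 1:1 for two classes; 1:2:1 for three) and reports all results
#' plus the best fit, defined as the largest p-value with ties broken by
#' the listed order.
#'
#' @param observed class counts (2 or 3 classes)
#' @return list with elements \code{best} (ratio label) and \code{results}
#'   (named list of \linkS4class{SegregationResult})
#' @examples
#' testStandardRatios(c(431, 147))$best   # "3:1"
#' @export
testStandardRatios <- function(observed) {
  fits <- .STANDARD_RATIOS[lengths(.STANDARD_RATIOS) == length(observed)]
  if (!length(fits))
    stop("no standard ratio has ", length(observed), " classes")
  results <- lapply(fits, chiSquareGof, observed = observed)
  ps <- vapply(results, pValue, 0)
  list(best = names(results)[which.max(ps)], results = results)
}
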