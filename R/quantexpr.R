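#' Relative expression by the Livak 2^-ddCt method
#'
#' Per sample, replicate Ct values are averaged on the cycle scale for each
#' gene; \eqn{\Delta Ct = \bar{Ct}_{target} - \bar{Ct}_{reference}};
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}}; the
#' fold change is \eqn{2^{-\Delta\Delta Ct}} (amplification efficiency
#' fixed at 2). The calibrator's fold change is exactly 1. Spread is
#' propagated from the replicate SDs of the two genes,
#' \eqn{sd_{\Delta Ct} = \sqrt{sd_t^2 + sd_r^2}}, and reported as the fold
#' range \eqn{2^{-(\Delta\Delta Ct \pm sd)}}.
#'
#' @param ct data.frame with columns \code{sample}, \code{gene} ("target" /
#'   "reference"), \code{replicate}, \code{ct} (cycles, > 0)
#' @param calibrator sample id of the calibrator
#' @return data.frame, one row per sample: \code{sample, delta_ct,
#'   sd_delta_ct, ddct, fold, fold_lower, fold_upper}
#' @examples
#' tab <- simulateCtTable(c(stem = 3), calibrator = "cal", noiseSd = 0,
#'                        seed = 1)
#' relativeExpression(tab, "cal")
#' @export
relativeExpression <- function(ct, calibrator) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(is.na(ct$ct) | ct$ct <= 0))
    stop("Ct values must be positive")
  if (!all(ct$gene %in% c("target", "reference")))
    stop("gene must be 'target' or 'reference'")
  if (!calibrator %in% ct$sample)
    stop("calibrator sample '", calibrator, "' not in the table")
  samples <- unique(ct$sample)
  per <- lapply(samples, function(s) {
    for (g in c("target", "reference"))
      if (!any(ct$sample == s & ct$gene == g))
        stop("sample '", s, "' lacks ", g, "-gene Ct values")
    tCt <- ct$ct[ct$sample == s & ct$gene == "target"]
    rCt <- ct$ct[ct$sample == s & ct$gene == "reference"]
    sdT <- if (length(tCt) > 1) sd(tCt) else 0
    sdR <- if (length(rCt) > 1) sd(rCt) else 0
    c(dct = mean(tCt) - mean(rCt), sd = sqrt(sdT^2 + sdR^2))
  })
  dct <- vapply(per, `[[`, 0, "dct")
  sdd <- vapply(per, `[[`, 0, "sd")
  ddct <- dct - dct[samples == calibrator]
  data.frame(sample = samples, delta_ct = dct, sd_delta_ct = sdd,
             ddct = ddct, fold = 2^(-ddct),
             fold_lower = 2^(-(ddct + sdd)), fold_upper = 2^(-(ddct - sdd)),
             row.names = NULL)
}

#' Ratio of two fold changes
#'
#' Convenience for statements like "x-fold lower in tissue A than B".
#'
#' @param exprA,exprB fold changes; \code{exprB} must be positive
#' @return \code{exprA / exprB}
#' @export
foldDifference <- function(exprA, exprB) {
  if (any(exprB <= 0)) stop("denominator fold change must be positive")
  exprA / exprB
}
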