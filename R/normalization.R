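#' Compute the fascia-anchored normalization factor
#'
#' From the original GSM of the segmented posterior renal fascia (medF0) the
#' dimensionless factor Fn = |medF0 - 200| / medF0 is derived. The transfer
#' function then multiplies every pixel by (1 + Fn) when medF0 <= 200 and by
#' (1 - Fn) when medF0 > 200; under the absolute-value reading both branches
#' are the single linear map r * 200 / medF0, which drives the fascia GSM to
#' the anchor level 200. Worked example: medF0 = 220 gives Fn = 20/220 =
#' 0.0909..., printed 0.09 at two decimals, and pixel 50 maps to
#' 50 * (1 - 0.09) = 45.5, rounded to 46.
#'
#' The literal signed form (medF0 - 200)/medF0 — negative below the anchor,
#' which would darken instead of brighten dark-fascia images — is available
#' behind \code{literalSign = TRUE} for auditability only.
#'
#' @param medF0 original fascia GSM, a gray level > 0.
#' @param literalSign keep the signed factor instead of its absolute value.
#' @return A \linkS4class{NormalizationFactor}.
#' @export
computeNormalizationFactor <- function(medF0, literalSign = FALSE) {
  if (!is.finite(medF0) || medF0 <= 0)
    stop("degenerate fascia reference: medF0 must be > 0 (got ", medF0, ")")
  fn <- (medF0 - 200) / medF0
  if (!literalSign) fn <- abs(fn)
  new("NormalizationFactor", medF0 = medF0, Fn = fn, targetLevel = 200,
      scale = 200 / medF0, literalSign = literalSign)
}

effectiveScale <- function(factor, policy) {
  if (policy == "exact_factor" && !factor@literalSign) {
    # both branches reduce to the single slope 200/medF0; computing it
    # directly avoids a 1-ulp discrepancy with the branch form at exact
    # half-integer products
    return(factor@scale)
  }
  fn <- factor@Fn
  if (policy == "paper_compat") fn <- round(fn, 2L)
  if (factor@medF0 <= 200) 1 + fn else 1 - fn
}

#' Apply the normalization transfer function to gray levels
#'
#' Maps each input gray level r to clip(round(r * s), 0, 255) where s is
#' (1 + Fn) for medF0 <= 200 and (1 - Fn) for medF0 > 200, rounding half
#' away from zero. Under the default \code{exact_factor} policy Fn is used
#' at full precision (s is exactly 200 / medF0); under \code{paper_compat}
#' Fn is first rounded to two decimals, reproducing the published worked
#' example (medF0 220, r 50 -> 46). The map is monotone non-decreasing, so
#' pixel rank order within any region is preserved.
#'
#' @param r gray level(s) in \[0, 255\] (vectorized).
#' @param factor a \linkS4class{NormalizationFactor}.
#' @param policy \code{"exact_factor"} (default) or \code{"paper_compat"}.
#' @return Integer gray level(s) in \[0, 255\].
#' @export
transferFunction <- function(r, factor,
                             policy = c("exact_factor", "paper_compat")) {
  policy <- match.arg(policy)
  stopifnot(is(factor, "NormalizationFactor"))
  if (any(r < 0 | r > 255)) stop("input gray levels must lie in [0, 255]")
  as.integer(clip255(roundHalfAway(r * effectiveScale(factor, policy))))
}

#' Normalize a whole image to the fascia anchor
#'
#' Computes the GSM of the fascia region, derives the normalization factor,
#' and applies the transfer function to every pixel of the image — not only
#' to the fascia — so the whole image is rescaled in accordance with the
#' change in the segmented fascia. For a fascia region with an odd pixel
#' count the recomputed fascia GSM after normalization equals 200 exactly
#' under the \code{exact_factor} policy (the transfer is monotone, so it
#' maps the median pixel to round(medF0 * 200 / medF0) = 200).
#'
#' @param image a \linkS4class{GrayImage}.
#' @param fasciaROI the fascia \linkS4class{PolygonROI}.
#' @param policy rounding policy passed to [transferFunction()].
#' @param literalSign audit flag passed to [computeNormalizationFactor()].
#' @return A list with elements \code{image} (the normalized
#'   \linkS4class{GrayImage}, whose \code{meta$normalization} records medF0,
#'   Fn, policy and the number of clipped pixels) and \code{factor} (the
#'   \linkS4class{NormalizationFactor}).
#' @export
normalizeImage <- function(image, fasciaROI,
                           policy = c("exact_factor", "paper_compat"),
                           literalSign = FALSE) {
  policy <- match.arg(policy)
  stopifnot(is(image, "GrayImage"), is(fasciaROI, "PolygonROI"))
  if (fasciaROI@label != "fascia")
    stop("normalization requires the fascia ROI, got label '", fasciaROI@label, "'")
  mask <- rasterizePolygon(fasciaROI, imgWidth(image), imgHeight(image))
  medF0 <- gsm(computeGSM(regionPixels(image, mask)))
  if (medF0 <= 0)
    stop("degenerate fascia reference: fascia GSM is 0, cannot normalize")
  factor <- computeNormalizationFactor(medF0, literalSign = literalSign)
  # the transfer depends on the gray level only: one 256-entry lookup
  lut <- transferFunction(0:255, factor, policy)
  sEff <- effectiveScale(factor, policy)
  raw <- roundHalfAway((0:255) * sEff)
  clipped <- sum(tabulate(image@pixels + 1L, nbins = 256L)[raw < 0 | raw > 255])
  px <- matrix(lut[image@pixels + 1L], nrow = imgHeight(image))
  meta <- image@meta
  meta$normalization <- list(medF0 = medF0, Fn = factor@Fn, policy = policy,
                             literalSign = literalSign, clipCount = clipped)
  out <- GrayImage(px, sourceId = image@sourceId, meta = meta)
  list(image = out, factor = factor)
}
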