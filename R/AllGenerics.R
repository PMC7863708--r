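#' Accessors for image and region objects
#'
#' @param x a \linkS4class{GrayImage}, \linkS4class{RegionMask},
#'   \linkS4class{GSMResult}, \linkS4class{BrightnessRanges} or
#'   \linkS4class{BrightnessDistribution}.
#' @return \code{imgWidth}/\code{imgHeight}: integer pixels.
#'   \code{intensities}: the integer pixel matrix. \code{nInside}: number of
#'   pixels inside a mask. \code{gsm}: the gray-scale median.
#'   \code{nBands}/\code{bandTable}: band count / band data.frame.
#'   \code{percentages}: named per-band percentages. \code{rangeSource}:
#'   provenance flag of the band configuration.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgWidth", function(x) standardGeneric("imgWidth"))
#' @rdname accessors
#' @export
setGeneric("imgHeight", function(x) standardGeneric("imgHeight"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("nInside", function(x) standardGeneric("nInside"))
#' @rdname accessors
#' @export
setGeneric("gsm", function(x) standardGeneric("gsm"))
#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))
#' @rdname accessors
#' @export
setGeneric("bandTable", function(x) standardGeneric("bandTable"))
#' @rdname accessors
#' @export
setGeneric("percentages", function(x) standardGeneric("percentages"))
#' @rdname accessors
#' @export
setGeneric("rangeSource", function(x) standardGeneric("rangeSource"))

setMethod("imgWidth", "GrayImage", function(x) ncol(x@pixels))
setMethod("imgHeight", "GrayImage", function(x) nrow(x@pixels))
setMethod("intensities", "GrayImage", function(x) x@pixels)
setMethod("imgWidth", "RegionMask", function(x) ncol(x@inside))
setMethod("imgHeight", "RegionMask", function(x) nrow(x@inside))
setMethod("nInside", "RegionMask", function(x) sum(x@inside))
setMethod("gsm", "GSMResult", function(x) x@gsm)
setMethod("nBands", "BrightnessRanges", function(x) nrow(x@bands))
setMethod("bandTable", "BrightnessRanges", function(x) x@bands)
setMethod("rangeSource", "BrightnessRanges", function(x) x@source)
setMethod("nBands", "BrightnessDistribution", function(x) length(x@counts))
setMethod("bandTable", "BrightnessDistribution", function(x) x@bands)
setMethod("percentages", "BrightnessDistribution", function(x) {
  stats::setNames(x@percentage, x@bands$tissue)
})

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d px [%d, %d]  source: %s\n",
              imgWidth(object), imgHeight(object),
              min(object@pixels), max(object@pixels),
              if (nzchar(object@sourceId)) object@sourceId else "<unset>"))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "PolygonROI", function(object) {
  cat(sprintf("PolygonROI '%s' with %d vertices\n",
              object@label, nrow(object@vertices)))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask %d x %d px, %d inside (%.1f%%)\n",
              imgWidth(object), imgHeight(object), nInside(object),
              100 * nInside(object) / length(object@inside)))
})

setMethod("show", "GSMResult", function(object) {
  cat(sprintf("GSM %.1f  (n = %d, mean = %.2f, sd = %.2f, range [%d, %d])\n",
              object@gsm, object@n, object@mean, object@sd,
              object@min, object@max))
})

setMethod("show", "BrightnessRanges", function(object) {
  cat(sprintf("BrightnessRanges: %d bands tiling [0, 255]  (source: %s)\n",
              nBands(object), object@source))
  b <- object@bands
  cat(paste(sprintf("  [%3d-%3d] %-24s %s", b$lo, b$hi, b$tissue, b$color),
            collapse = "\n"), "\n")
})

setMethod("show", "BrightnessDistribution", function(object) {
  cat(sprintf("BrightnessDistribution over %d bands, n = %d pixels\n",
              nBands(object), object@n))
  b <- object@bands
  cat(paste(sprintf("  [%3d-%3d] %-24s %7.3f%%", b$lo, b$hi, b$tissue,
                    object@percentage), collapse = "\n"), "\n")
})

setMethod("show", "NormalizationFactor", function(object) {
  cat(sprintf("NormalizationFactor: medF0 = %.1f, Fn = %.4f, scale = %.4f -> fascia GSM %g%s\n",
              object@medF0, object@Fn, object@scale, object@targetLevel,
              if (object@literalSign) "  [literal signed Fn]" else ""))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %d x %d px, speckle scale %.2f, seed %d\n",
              object@width, object@height, object@speckleScale, object@seed))
  cat(sprintf("  means: %s\n",
              paste(sprintf("%s=%g", names(object@means), object@means),
                    collapse = ", ")))
})

setMethod("show", "StatReport", function(object) {
  cat(sprintf("StatReport  category: %s  grouped by: %s  alpha = %g  (%d tests, uncorrected)\n",
              object@category, object@groupBy, object@alpha, object@nTests))
  om <- object@omnibus
  sig <- om$variable[om$p < object@alpha]
  cat(sprintf("  Kruskal-Wallis: %d/%d variables significant%s\n",
              length(sig), nrow(om),
              if (length(sig)) paste0(" (", paste(sig, collapse = ", "), ")") else ""))
  pw <- object@pairwise
  if (nrow(pw)) {
    agg <- stats::aggregate(significant ~ group_a + group_b, data = pw, FUN = sum)
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %s vs %s: %d significant variables\n",
                  agg$group_a[i], agg$group_b[i], agg$significant[i]))
  }
})
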