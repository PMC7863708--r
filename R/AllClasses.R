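#' @import methods
NULL

#' GrayImage: an 8-bit grayscale raster
#'
#' The object every processing stage transforms: a height x width integer
#' matrix of gray levels in \[0, 255\] plus acquisition metadata. Pixel
#' coordinates used by ROIs are 0-based with the origin at the top-left
#' corner, x increasing rightward and y downward; internally the raster is
#' stored as a matrix indexed \code{[y + 1, x + 1]}.
#'
#' @slot pixels integer matrix (rows = height, columns = width), values in
#'   \[0, 255\].
#' @slot sourceId opaque identifier of the acquisition (file name, phantom
#'   id, ...).
#' @slot meta named list of free-form metadata (e.g. normalization records).
#' @exportClass GrayImage
setClass("GrayImage",
  slots = c(pixels = "matrix", sourceId = "character", meta = "list"),
  prototype = list(sourceId = "", meta = list()))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric/integer matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
  if (anyNA(p)) return("pixels contain NA")
  if (any(p != floor(p))) return("pixel intensities must be integers")
  if (min(p) < 0 || max(p) > 255) return("pixel intensities must lie in [0, 255]")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels integer matrix of gray levels, rows = height.
#' @param sourceId identifier string.
#' @param meta named list of metadata.
#' @return A validated \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(0:3, 2, 2))
#' imgWidth(img)
#' @export
GrayImage <- function(pixels, sourceId = "", meta = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  new("GrayImage", pixels = pixels, sourceId = sourceId, meta = meta)
}

#' PolygonROI: a manually drawn closed contour
#'
#' @slot label region label, one of \code{"fascia"} or \code{"kidney"}.
#' @slot vertices n x 2 numeric matrix of (x, y) pixel coordinates, 0-based.
#' @exportClass PolygonROI
setClass("PolygonROI", slots = c(label = "character", vertices = "matrix"))

setValidity("PolygonROI", function(object) {
  if (length(object@label) != 1L || !object@label %in% c("fascia", "kidney"))
    return(sprintf("unknown ROI label '%s' (must be 'fascia' or 'kidney')",
                   paste(object@label, collapse = ",")))
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L) return("vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 3L) return("a polygon ROI needs at least 3 vertices")
  if (anyNA(v)) return("vertices contain NA")
  TRUE
})

#' Construct a PolygonROI
#'
#' @param label \code{"fascia"} or \code{"kidney"}.
#' @param vertices n x 2 matrix (or two-column data.frame) of 0-based (x, y)
#'   pixel coordinates in drawing order; the contour is implicitly closed.
#' @return A validated \linkS4class{PolygonROI}.
#' @export
polygonROI <- function(label, vertices) {
  v <- as.matrix(vertices)
  colnames(v) <- c("x", "y")
  new("PolygonROI", label = as.character(label), vertices = v)
}

#' RegionMask: the rasterized pixel set of an ROI
#'
#' @slot inside logical matrix with the dimensions of the paired image;
#'   TRUE marks pixels whose center falls inside (or on the boundary of)
#'   the polygon.
#' @exportClass RegionMask
setClass("RegionMask", slots = c(inside = "matrix"))

setValidity("RegionMask", function(object) {
  m <- object@inside
  if (!is.logical(m)) return("inside must be a logical matrix")
  if (nrow(m) < 1L || ncol(m) < 1L) return("mask must be at least 1 x 1")
  TRUE
})

#' GSMResult: first-order gray-level statistics of a region
#'
#' The gray-scale median (GSM) marks the division between the pixels with
#' greater and lesser brightness within the segmented area: the middle order
#' statistic for odd n, the mean of the two middle order statistics for even
#' n (so values ending in .5 are possible and are propagated unrounded).
#'
#' @slot gsm numeric, the median gray level.
#' @slot n integer pixel count.
#' @slot min,max integer extremes.
#' @slot mean,sd numeric first moments (sd is 0 for n = 1).
#' @exportClass GSMResult
setClass("GSMResult",
  slots = c(gsm = "numeric", n = "integer", min = "integer",
            max = "integer", mean = "numeric", sd = "numeric"))

setValidity("GSMResult", function(object) {
  if (object@n < 1L) return("n must be >= 1")
  if (object@min > object@gsm || object@gsm > object@max)
    return("min <= gsm <= max violated")
  TRUE
})

#' BrightnessRanges: the labeled intensity bands of the virtual histology
#'
#' An ordered set of closed intervals that tile \[0, 255\] exactly, each
#' carrying a probable-tissue label and a display color. The default
#' configuration has 14 bands.
#'
#' @slot bands data.frame with columns \code{lo}, \code{hi} (inclusive gray
#'   levels), \code{tissue} (label), \code{color} (hex "#RRGGBB").
#' @slot source provenance flag: \code{"fallback_uniform"} for the built-in
#'   uniform tiling, \code{"config"} for user-supplied files, or
#'   \code{"custom"}.
#' @exportClass BrightnessRanges
setClass("BrightnessRanges", slots = c(bands = "data.frame", source = "character"))

setValidity("BrightnessRanges", function(object) {
  b <- object@bands
  need <- c("lo", "hi", "tissue", "color")
  if (!all(need %in% names(b))) return("bands need columns lo, hi, tissue, color")
  if (nrow(b) < 1L) return("at least one band required")
  if (any(b$lo != floor(b$lo)) || any(b$hi != floor(b$hi)))
    return("band bounds must be integers")
  if (b$lo[1L] != 0L) return("first band must start at 0")
  if (b$hi[nrow(b)] != 255L) return("last band must end at 255")
  if (any(b$hi < b$lo)) return("band with hi < lo")
  if (nrow(b) > 1L && any(b$lo[-1L] != b$hi[-nrow(b)] + 1L))
    return("bands must be contiguous (lo[i+1] == hi[i] + 1): they must tile [0,255]")
  TRUE
})

#' Construct a BrightnessRanges configuration
#'
#' @param bands data.frame with integer columns \code{lo}, \code{hi} and
#'   character columns \code{tissue}, \code{color}; bands must be sorted,
#'   non-overlapping and jointly tile \[0, 255\].
#' @param source provenance string stored with the object.
#' @return A validated \linkS4class{BrightnessRanges}.
#' @seealso [defaultBrightnessRanges()]
#' @export
brightnessRanges <- function(bands, source = "custom") {
  bands <- as.data.frame(bands)
  bands$lo <- as.integer(bands$lo); bands$hi <- as.integer(bands$hi)
  new("BrightnessRanges", bands = bands, source = source)
}

#' BrightnessDistribution: pixel counts over the brightness bands
#'
#' @slot bands the \linkS4class{BrightnessRanges} bands data.frame used.
#' @slot counts integer per-band pixel counts (sum to n).
#' @slot percentage numeric per-band percentages (sum to 100).
#' @slot n total region pixel count.
#' @slot source provenance flag inherited from the ranges.
#' @exportClass BrightnessDistribution
setClass("BrightnessDistribution",
  slots = c(bands = "data.frame", counts = "integer",
            percentage = "numeric", n = "integer", source = "character"))

setValidity("BrightnessDistribution", function(object) {
  if (sum(object@counts) != object@n) return("counts must sum to n")
  if (abs(sum(object@percentage) - 100) > 1e-9)
    return("percentages must sum to 100 within 1e-9")
  TRUE
})

#' NormalizationFactor: the fascia-anchored linear map
#'
#' Holds the original fascia GSM (medF0), the dimensionless factor
#' Fn = |medF0 - 200| / medF0, the fixed anchor level 200, and the effective
#' slope 200 / medF0. Both transfer branches (medF0 <= 200: r(1 + Fn);
#' medF0 > 200: r(1 - Fn)) reduce to the single map r * 200 / medF0.
#'
#' @slot medF0 original fascia gray-scale median (> 0).
#' @slot Fn dimensionless normalization factor (>= 0; may be negative only
#'   under the literal signed reading, kept for audit).
#' @slot targetLevel the anchor gray level, constant 200.
#' @slot scale effective slope applied to every pixel.
#' @slot literalSign logical; TRUE if Fn kept the signed form
#'   (medF0 - 200)/medF0 instead of its absolute value.
#' @exportClass NormalizationFactor
setClass("NormalizationFactor",
  slots = c(medF0 = "numeric", Fn = "numeric", targetLevel = "numeric",
            scale = "numeric", literalSign = "logical"))

setValidity("NormalizationFactor", function(object) {
  if (object@medF0 <= 0) return("medF0 must be > 0")
  if (object@targetLevel != 200) return("targetLevel is fixed at 200")
  TRUE
})

#' PhantomSpec: geometry and texture of the synthetic ultrasound phantom
#'
#' Defines a speckle-textured B-mode-like test image: an elliptical kidney
#' (cortex) containing a brighter elliptical sinus, over a dark background,
#' with a bright posterior fascia band that does not intersect the kidney.
#' Pixels are clip(round(region_mean * speckle)) with multiplicative
#' unit-mean Rayleigh speckle attenuated by \code{speckleScale}.
#'
#' @slot width,height raster size in pixels.
#' @slot kidneyCenter,kidneyAxes,sinusAxes ellipse geometry (pixels).
#' @slot fasciaTop,fasciaThickness posterior band placement (pixels).
#' @slot means named numeric: mean gray level of background, cortex, sinus,
#'   fascia, each in (0, 255).
#' @slot speckleScale speckle contrast in \[0, 1\]: 0 = noiseless,
#'   1 = fully developed Rayleigh texture.
#' @slot seed integer RNG seed; generation is deterministic given the seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  slots = c(width = "integer", height = "integer",
            kidneyCenter = "numeric", kidneyAxes = "numeric",
            sinusAxes = "numeric", fasciaTop = "integer",
            fasciaThickness = "integer", means = "numeric",
            speckleScale = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@width < 16L || object@height < 16L)
    return("phantom must be at least 16 x 16")
  m <- object@means
  if (!all(c("background", "cortex", "sinus", "fascia") %in% names(m)))
    return("means must name background, cortex, sinus, fascia")
  if (any(m <= 0) || any(m >= 255)) return("region means must lie in (0, 255)")
  if (any(object@kidneyAxes <= 0) || any(object@sinusAxes <= 0))
    return("degenerate (zero-area) ellipse")
  if (any(object@sinusAxes >= object@kidneyAxes))
    return("sinus ellipse must be strictly inside the kidney ellipse")
  if (object@fasciaThickness < 1L) return("degenerate fascia band")
  if (object@fasciaTop <= object@kidneyCenter[2L] + object@kidneyAxes[2L])
    return("fascia band intersects the kidney ellipse")
  if (object@fasciaTop + object@fasciaThickness > object@height)
    return("fascia band exceeds the image")
  if (object@speckleScale < 0 || object@speckleScale > 1)
    return("speckleScale must be in [0, 1]")
  TRUE
})

#' StatReport: multi-operator comparability analysis for one image category
#'
#' @slot category image category analyzed (random, standardized,
#'   random-normalized, standardized-normalized).
#' @slot groupBy grouping variable ("physician_id" or "device_id").
#' @slot alpha significance level (default 0.05).
#' @slot omnibus data.frame: per variable, the Kruskal-Wallis H, df, p.
#' @slot pairwise data.frame: per group pair and variable, the rank-sum W,
#'   p, and significance flag at alpha.
#' @slot nTests total number of hypothesis tests performed (no
#'   multiple-testing correction is applied; the count is reported instead).
#' @exportClass StatReport
setClass("StatReport",
  slots = c(category = "character", groupBy = "character", alpha = "numeric",
            omnibus = "data.frame", pairwise = "data.frame", nTests = "integer"))

setValidity("StatReport", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0, 1)")
  if (nrow(object@omnibus) && any(object@omnibus$p < 0 | object@omnibus$p > 1, na.rm = TRUE))
    return("omnibus p-values outside [0, 1]")
  if (nrow(object@pairwise)) {
    if (any(object@pairwise$p < 0 | object@pairwise$p > 1, na.rm = TRUE))
      return("pairwise p-values outside [0, 1]")
    ok <- object@pairwise$significant == (object@pairwise$p < object@alpha)
    if (!all(ok, na.rm = TRUE)) return("significant flag inconsistent with p < alpha")
  }
  TRUE
})
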