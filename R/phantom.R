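#' Construct a synthetic phantom specification
#'
#' Builds the geometry of a speckle-textured test image: an elliptical
#' kidney containing a brighter elliptical sinus over a dark background,
#' with a bright posterior fascia band below (never intersecting) the
#' kidney. Geometry defaults scale with the raster so phantoms of any size
#' share the same layout; the default raster is 800 x 600, the resolution
#' the acquisition hardware exports. Region means default to background 40,
#' cortex 90, sinus 150, fascia 220 gray levels — an echogenicity ordering
#' typical of B-mode renal images. Speckle is multiplicative with unit mean
#' (see [generatePhantom()]); the default contrast 0.25 emulates
#' display-stage texture after log compression and scan-conversion
#' smoothing, keeping the region GSM within a few gray levels of the region
#' mean.
#'
#' @param width,height raster size in pixels.
#' @param means named numeric vector of region mean gray levels
#'   (background, cortex, sinus, fascia), each in (0, 255).
#' @param speckleScale speckle contrast in \[0, 1\] (0 = noiseless).
#' @param seed RNG seed; phantom generation is deterministic given the seed.
#' @param kidneyCenter,kidneyAxes,sinusAxes,fasciaTop,fasciaThickness
#'   optional geometry overrides (pixels); defaults are proportional to the
#'   raster size, with an odd fascia-band thickness.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(width = 800L, height = 600L,
                        means = c(background = 40, cortex = 90,
                                  sinus = 150, fascia = 220),
                        speckleScale = 0.25, seed = 1L,
                        kidneyCenter = NULL, kidneyAxes = NULL,
                        sinusAxes = NULL, fasciaTop = NULL,
                        fasciaThickness = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.null(kidneyCenter)) kidneyCenter <- c(0.50 * width, 0.42 * height)
  if (is.null(kidneyAxes))   kidneyAxes   <- c(0.33 * width, 0.27 * height)
  if (is.null(sinusAxes))    sinusAxes    <- c(0.16 * width, 0.12 * height)
  if (is.null(fasciaTop))    fasciaTop    <- as.integer(round(0.78 * height))
  if (is.null(fasciaThickness)) {
    t <- max(3L, as.integer(round(0.07 * height)))
    if (t %% 2L == 0L) t <- t + 1L  # odd thickness -> odd fascia ROI count
    fasciaThickness <- t
  }
  new("PhantomSpec", width = width, height = height,
      kidneyCenter = as.numeric(kidneyCenter),
      kidneyAxes = as.numeric(kidneyAxes), sinusAxes = as.numeric(sinusAxes),
      fasciaTop = as.integer(fasciaTop),
      fasciaThickness = as.integer(fasciaThickness),
      means = means, speckleScale = speckleScale, seed = as.integer(seed))
}

# Region id raster: 1 background, 2 cortex, 3 sinus, 4 fascia.
regionMap <- function(spec) {
  w <- spec@width; h <- spec@height
  x <- matrix(rep(0:(w - 1L), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1L), times = w), nrow = h)
  cx <- spec@kidneyCenter[1L]; cy <- spec@kidneyCenter[2L]
  ids <- matrix(1L, nrow = h, ncol = w)
  inKid <- ((x - cx) / spec@kidneyAxes[1L])^2 + ((y - cy) / spec@kidneyAxes[2L])^2 <= 1
  inSin <- ((x - cx) / spec@sinusAxes[1L])^2 + ((y - cy) / spec@sinusAxes[2L])^2 <= 1
  ids[inKid] <- 2L
  ids[inSin] <- 3L
  ids[y >= spec@fasciaTop & y < spec@fasciaTop + spec@fasciaThickness] <- 4L
  ids
}

# The delineating ROIs of a phantom. The fascia rectangle spans the band
# with odd width x odd height so its pixel count is odd (the GSM of an
# odd-count region is a single order statistic, which the monotone
# normalization transfer maps exactly onto the anchor).
phantomFasciaROI <- function(spec) {
  x0 <- as.integer(ceiling(0.10 * spec@width))
  x1 <- as.integer(floor(0.90 * spec@width))
  if ((x1 - x0 + 1L) %% 2L == 0L) x1 <- x1 - 1L
  y0 <- spec@fasciaTop
  y1 <- spec@fasciaTop + spec@fasciaThickness - 1L
  polygonROI("fascia", rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
}

phantomKidneyROI <- function(spec, nVertices = 72L) {
  th <- 2 * pi * (seq_len(nVertices) - 1L) / nVertices
  v <- cbind(spec@kidneyCenter[1L] + 0.97 * spec@kidneyAxes[1L] * cos(th),
             spec@kidneyCenter[2L] + 0.97 * spec@kidneyAxes[2L] * sin(th))
  polygonROI("kidney", v)
}

# Pixel synthesis shared by generatePhantom and generateStudy: multiplicative
# unit-mean Rayleigh speckle attenuated toward 1 by the contrast s,
# pixel = clip(round(mean * (1 + s (R - 1)))).
phantomPixels <- function(spec, means, seed) {
  ids <- regionMap(spec)
  meanMap <- means[ids]
  n <- length(meanMap)
  withSeed(seed, {
    u <- pmax(stats::runif(n), 1e-300)
    rayl <- sqrt(-2 * log(u)) * sqrt(2 / pi)  # Rayleigh, E[rayl] = 1
    speckle <- 1 + spec@speckleScale * (rayl - 1)
    matrix(as.integer(clip255(roundHalfAway(meanMap * speckle))),
           nrow = spec@height)
  })
}

#' Generate a synthetic ultrasound phantom
#'
#' Produces a speckled test image together with the fascia and kidney ROIs
#' that delineate its generated structures. Generation is deterministic
#' given \code{spec@seed}; with \code{speckleScale = 0} every region is
#' exactly its configured mean.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list with elements \code{image} (\linkS4class{GrayImage}),
#'   \code{fasciaROI} and \code{kidneyROI} (\linkS4class{PolygonROI}).
#' @examples
#' ph <- generatePhantom(phantomSpec(width = 120, height = 90, seed = 7))
#' ph$image
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  px <- phantomPixels(spec, spec@means, spec@seed)
  img <- GrayImage(px, sourceId = sprintf("phantom_seed%d", spec@seed),
                   meta = list(phantom = list(seed = spec@seed,
                                              speckleScale = spec@speckleScale,
                                              means = as.list(spec@means))))
  list(image = img, fasciaROI = phantomFasciaROI(spec),
       kidneyROI = phantomKidneyROI(spec))
}

#' Apply an acquisition gain/offset to an image
#'
#' Models the operator- and device-dependent amplification of B-mode
#' acquisition as the linear map pixel -> clip(round(gain * pixel + offset)).
#'
#' @param image a \linkS4class{GrayImage}.
#' @param gain multiplicative gain (> 0).
#' @param offset additive offset in gray levels.
#' @return A \linkS4class{GrayImage}.
#' @export
applyOperatorEffect <- function(image, gain, offset = 0) {
  stopifnot(is(image, "GrayImage"), gain > 0)
  px <- matrix(as.integer(clip255(roundHalfAway(gain * image@pixels + offset))),
               nrow = imgHeight(image))
  GrayImage(px, sourceId = image@sourceId, meta = image@meta)
}

#' Define the operator effects of a simulated study
#'
#' One row per physician: the multiplicative gain and additive offset that
#' physician's habitual settings impose on the displayed gray levels. Under
#' the \code{random} acquisition method the physician's own gain/offset
#' apply in full; under the \code{standardized} method they are replaced by
#' the fixed study-wide preset values, identical for every physician.
#'
#' @param physician_id character vector of unique physician labels.
#' @param device_id character vector (recycled) of device labels.
#' @param gain numeric vector of gains (> 0).
#' @param offset numeric vector of offsets (gray levels).
#' @return A data.frame with one row per physician.
#' @export
operatorEffects <- function(physician_id, device_id = "dev1",
                            gain = 1, offset = 0) {
  if (anyDuplicated(physician_id))
    stop("duplicate physician_id in operator effects")
  if (any(gain <= 0)) stop("gain_multiplier must be > 0")
  data.frame(physician_id = as.character(physician_id),
             device_id = rep_len(as.character(device_id), length(physician_id)),
             gain = rep_len(gain, length(physician_id)),
             offset = rep_len(offset, length(physician_id)),
             stringsAsFactors = FALSE)
}

#' Generate a full multi-operator phantom study
#'
#' Emulates the study design: every patient's left and right kidney is
#' imaged by every physician under both acquisition methods, giving
#' n_patients x 2 sides x n_physicians x 2 methods images. Each (patient,
#' side) carries a random baseline perturbation of the region means
#' (normal, sd \code{patientSD}); each (patient, side, physician) has its
#' own speckle realization drawn from a hierarchically derived substream,
#' so the random and standardized acquisitions of one physician share the
#' same underlying tissue image and differ only by the applied gain/offset,
#' and adding a physician never changes another physician's images.
#'
#' @param nPatients number of patients (>= 1).
#' @param effects operator-effect table from [operatorEffects()].
#' @param spec a \linkS4class{PhantomSpec} (its seed is superseded by the
#'   derived substreams).
#' @param seed integer study seed; the study is fully reproducible from it.
#' @param dir if non-NULL, BMP images, ROI JSON files and a manifest CSV are
#'   written there; otherwise images are returned in memory.
#' @param patientSD sd (gray levels) of the per-(patient, side) normal
#'   perturbation of region means.
#' @param standardizedGain,standardizedOffset the fixed study-wide preset
#'   applied under the standardized method.
#' @return A list: \code{manifest} (data.frame with the acquisition columns
#'   plus \code{category}), \code{images} (named list of
#'   \linkS4class{GrayImage}, NULL when written to disk), \code{fasciaROI},
#'   \code{kidneyROI}, \code{dir}.
#' @export
generateStudy <- function(nPatients, effects, spec = phantomSpec(),
                          seed = 1L, dir = NULL, patientSD = 5,
                          standardizedGain = 1, standardizedOffset = 0) {
  stopifnot(nPatients >= 1, is(spec, "PhantomSpec"))
  if (anyDuplicated(effects$physician_id))
    stop("duplicate physician_id in operator effects")
  fasciaROI <- phantomFasciaROI(spec)
  kidneyROI <- phantomKidneyROI(spec)
  toDisk <- !is.null(dir)
  if (toDisk) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasciaPath <- file.path(dir, "fascia.roi.json")
    kidneyPath <- file.path(dir, "kidney.roi.json")
    writeROI(fasciaROI, fasciaPath)
    writeROI(kidneyROI, kidneyPath)
  } else {
    fasciaPath <- "fascia.roi.json"; kidneyPath <- "kidney.roi.json"
  }

  sides <- c("left", "right")
  methods <- c("random", "standardized")
  rows <- vector("list", nPatients * 2L * nrow(effects) * 2L)
  images <- if (toDisk) NULL else vector("list", length(rows))
  k <- 0L
  for (p in seq_len(nPatients)) {
    pid <- sprintf("pt%02d", p)
    for (s in sides) {
      baseline <- withSeed(mixSeed(seed, "baseline", p, s), {
        b <- spec@means + stats::rnorm(length(spec@means), 0, patientSD)
        pmin(pmax(b, 1), 254)
      })
      for (d in seq_len(nrow(effects))) {
        phys <- effects$physician_id[d]
        raw <- phantomPixels(spec, baseline,
                             mixSeed(seed, "speckle", p, s, phys))
        rawImg <- GrayImage(raw)
        for (m in methods) {
          g <- if (m == "random") effects$gain[d] else standardizedGain
          o <- if (m == "random") effects$offset[d] else standardizedOffset
          id <- sprintf("%s_%s_%s_%s", pid, s, phys, m)
          img <- applyOperatorEffect(rawImg, g, o)
          img@sourceId <- id
          path <- paste0(id, ".bmp")
          k <- k + 1L
          if (toDisk) {
            writeGrayBMP(img, file.path(dir, path))
          } else {
            images[[k]] <- img
          }
          rows[[k]] <- data.frame(
            patient_id = pid, side = s, physician_id = phys,
            device_id = effects$device_id[d], method = m, normalized = FALSE,
            image_path = path, fascia_roi_path = basename(fasciaPath),
            kidney_roi_path = basename(kidneyPath), stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$category <- categoryOf(manifest$method, manifest$normalized)
  if (!toDisk) names(images) <- manifest$image_path
  if (toDisk) writeManifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest, images = images,
       fasciaROI = fasciaROI, kidneyROI = kidneyROI, dir = dir)
}
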