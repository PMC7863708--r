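#' Analyze one image: GSM and brightness distribution of the kidney region
#'
#' The per-image procedure: (optionally) normalize the whole image to the
#' fascia anchor, rasterize the kidney contour, and compute the GSM,
#' descriptive statistics and 14-band brightness distribution of the kidney
#' region. Returns one result row suitable for [writeResultsTable()] and the
#' comparability analysis.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param kidneyROI the kidney \linkS4class{PolygonROI}.
#' @param fasciaROI the fascia \linkS4class{PolygonROI}; required when
#'   \code{normalize = TRUE}.
#' @param normalize apply the fascia-anchored normalization first.
#' @param ranges a \linkS4class{BrightnessRanges}.
#' @param policy rounding policy for the normalization transfer.
#' @param ids named list of identifier columns to prepend (patient_id,
#'   side, physician_id, device_id, method, ...).
#' @param pseudocolor if TRUE, also return the pseudocolor raster.
#' @return A list: \code{row} (one-row data.frame: identifiers, category,
#'   gsm, n_pixels, mean/sd/min/max, pct_01..pct_k, medF0/Fn when
#'   normalized, and the range provenance flag), \code{image} (the analyzed,
#'   possibly normalized, GrayImage), and \code{pseudocolor} (array or NULL).
#' @export
analyzeImage <- function(image, kidneyROI, fasciaROI = NULL,
                         normalize = FALSE,
                         ranges = defaultBrightnessRanges(),
                         policy = c("exact_factor", "paper_compat"),
                         ids = list(), pseudocolor = FALSE) {
  policy <- match.arg(policy)
  stopifnot(is(image, "GrayImage"), is(kidneyROI, "PolygonROI"))
  if (kidneyROI@label != "kidney")
    stop("kidney analysis requires the kidney ROI, got label '",
         kidneyROI@label, "'")
  medF0 <- NA_real_; fn <- NA_real_
  if (normalize) {
    if (is.null(fasciaROI))
      stop("usage error: normalization requested without a fascia ROI")
    norm <- normalizeImage(image, fasciaROI, policy = policy)
    image <- norm$image
    medF0 <- norm$factor@medF0
    fn <- norm$factor@Fn
  }
  mask <- rasterizePolygon(kidneyROI, imgWidth(image), imgHeight(image))
  px <- regionPixels(image, mask)
  g <- computeGSM(px)
  dist <- brightnessDistribution(px, ranges)
  pct <- as.list(dist@percentage)
  names(pct) <- sprintf("pct_%02d", seq_along(pct))
  method <- if (!is.null(ids$method)) ids$method else NA_character_
  row <- c(ids,
           list(normalized = normalize,
                category = if (!is.na(method)) categoryOf(method, normalize)
                           else NA_character_,
                gsm = g@gsm, n_pixels = g@n, mean = g@mean, sd = g@sd,
                min = g@min, max = g@max),
           pct,
           list(medF0 = medF0, Fn = fn, policy = if (normalize) policy else NA_character_,
                range_source = rangeSource(ranges)))
  list(row = as.data.frame(row, stringsAsFactors = FALSE),
       image = image,
       pseudocolor = if (pseudocolor) pseudocolorRender(image, mask, ranges) else NULL)
}

# Resolve one manifest record to in-memory objects, whatever the source.
loadRecord <- function(rec, study = NULL) {
  if (!is.null(study) && !is.null(study$images)) {
    list(image = study$images[[rec$image_path]],
         fascia = study$fasciaROI, kidney = study$kidneyROI)
  } else {
    base <- if (!is.null(study) && !is.null(study$dir)) study$dir else "."
    list(image = readGrayImage(file.path(base, rec$image_path)),
         fascia = readROI(file.path(base, rec$fascia_roi_path)),
         kidney = readROI(file.path(base, rec$kidney_roi_path)))
  }
}

#' Run the four-category study pipeline
#'
#' For every manifest record the raw acquisition contributes its own
#' category row (random or standardized) and, when a fascia ROI is present,
#' a second row for its normalized counterpart (random-normalized or
#' standardized-normalized) derived in-pipeline — normalized images are not
#' stored as separate acquisitions. Records whose files cannot be read are
#' excluded and logged, and the run continues; the exclusion log reconciles
#' input and output row counts. After the table is built, a
#' \linkS4class{StatReport} is produced for every category with at least
#' two groups.
#'
#' @param manifest manifest data.frame (from [readManifest()] or
#'   [generateStudy()]\code{$manifest}).
#' @param study optional study object from [generateStudy()] holding
#'   in-memory images and shared ROIs; when NULL, paths in the manifest are
#'   read from disk (relative to \code{dir}).
#' @param dir base directory for manifest paths when reading from disk.
#' @param ranges a \linkS4class{BrightnessRanges}.
#' @param policy normalization rounding policy.
#' @param groupBy grouping variable for the comparability reports.
#' @param alpha significance level.
#' @return A list: \code{results} (data.frame, up to 2 rows per record),
#'   \code{reports} (named list of \linkS4class{StatReport}, one per
#'   analyzable category), \code{exclusions} (data.frame of skipped records
#'   with reasons).
#' @export
runStudyPipeline <- function(manifest, study = NULL, dir = NULL,
                             ranges = defaultBrightnessRanges(),
                             policy = c("exact_factor", "paper_compat"),
                             groupBy = "physician_id", alpha = 0.05) {
  policy <- match.arg(policy)
  if (!is.null(dir) && is.null(study)) study <- list(dir = dir)
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, , drop = FALSE]
    ids <- list(patient_id = rec$patient_id, side = rec$side,
                physician_id = rec$physician_id, device_id = rec$device_id,
                method = rec$method)
    res <- tryCatch({
      obj <- loadRecord(rec, study)
      if (is.null(obj$image)) stop("image not found: ", rec$image_path)
      raw <- analyzeImage(obj$image, obj$kidney, ranges = ranges, ids = ids)
      norm <- analyzeImage(obj$image, obj$kidney, fasciaROI = obj$fascia,
                           normalize = TRUE, ranges = ranges,
                           policy = policy, ids = ids)
      rbind(raw$row, norm$row)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        image_path = rec$image_path, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
      message("excluded ", rec$image_path, ": ", conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  exclusions <- if (length(excl)) do.call(rbind, excl)
               else data.frame(image_path = character(0), reason = character(0))

  reports <- list()
  if (!is.null(results)) {
    for (cat in unique(results$category)) {
      rep <- tryCatch(
        compareOperators(results, cat, groupBy = groupBy, alpha = alpha),
        error = function(e) NULL)
      if (!is.null(rep)) reports[[cat]] <- rep
    }
  }
  list(results = results, reports = reports, exclusions = exclusions)
}
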