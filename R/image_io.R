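#' Read a grayscale image (BMP, with PNG accepted as a courtesy)
#'
#' BMP is the canonical on-disk format of this tool; PNG files are accepted
#' on input for convenience (converted by Rec.601 luma if RGB) but output is
#' always BMP.
#'
#' @param path path to a \code{.bmp} or \code{.png} file.
#' @return A \linkS4class{GrayImage}.
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  magic <- readBin(path, "raw", n = 8L)
  isPNG <- length(magic) >= 8L &&
    identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
  if (!isPNG) return(readGrayBMP(path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) {
    px <- roundHalfAway(a * 255)
  } else {
    px <- lumaRec601(a[, , 1L] * 255, a[, , 2L] * 255, a[, , 3L] * 255)
  }
  GrayImage(matrix(as.integer(px), nrow = dim(a)[1L]), sourceId = basename(path))
}

#' Read / write a polygon ROI file
#'
#' ROI files are JSON with the schema
#' \code{{"label": "fascia"|"kidney", "vertices": [[x, y], ...]}} where the
#' vertices are 0-based pixel coordinates (origin top-left, x rightward,
#' y downward) in drawing order. One ROI per file; at least 3 vertices.
#'
#' @param path path to the ROI file.
#' @return \code{readROI}: a \linkS4class{PolygonROI}.
#' @export
readROI <- function(path) {
  if (!file.exists(path)) stop("cannot read ROI: file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$label) || is.null(obj$vertices))
    stop("ROI file must contain 'label' and 'vertices': ", path)
  v <- obj$vertices
  if (is.list(v)) v <- do.call(rbind, v)
  v <- matrix(as.numeric(v), ncol = 2L)
  polygonROI(obj$label, v)
}

#' @rdname readROI
#' @param roi a \linkS4class{PolygonROI} to serialize.
#' @export
writeROI <- function(roi, path) {
  stopifnot(is(roi, "PolygonROI"))
  v <- roi@vertices
  dimnames(v) <- NULL
  jsonlite::write_json(list(label = roi@label, vertices = v), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

manifestColumns <- c("patient_id", "side", "physician_id", "device_id",
                     "method", "normalized", "image_path",
                     "fascia_roi_path", "kidney_roi_path")

#' Image category from acquisition method and normalization state
#'
#' The four categories of the study design: \code{random},
#' \code{standardized}, \code{random-normalized},
#' \code{standardized-normalized}.
#'
#' @param method \code{"random"} or \code{"standardized"}.
#' @param normalized logical.
#' @return Character vector of category names.
#' @export
categoryOf <- function(method, normalized) {
  stopifnot(all(method %in% c("random", "standardized")))
  paste0(method, ifelse(as.logical(normalized), "-normalized", ""))
}

#' Read / write an acquisition manifest
#'
#' The manifest is a CSV (UTF-8, header row) with one acquisition per row
#' and columns \code{patient_id, side, physician_id, device_id, method,
#' normalized, image_path, fascia_roi_path, kidney_roi_path}. \code{method}
#' must be \code{random} or \code{standardized}; \code{side} must be
#' \code{left} or \code{right}. Each row's category follows from
#' [categoryOf()].
#'
#' @param path path to the manifest CSV.
#' @return \code{readManifest}: a data.frame with the columns above plus a
#'   derived \code{category} column; zero rows for a header-only file.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(manifestColumns, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  df$normalized <- as.logical(df$normalized)
  if (anyNA(df$normalized)) stop("manifest column 'normalized' must be TRUE/FALSE")
  bad <- setdiff(unique(df$method), c("random", "standardized"))
  if (length(bad))
    stop("invalid acquisition method(s) in manifest: ", paste(bad, collapse = ", "))
  badSide <- setdiff(unique(df$side), c("left", "right"))
  if (length(badSide))
    stop("invalid side value(s) in manifest: ", paste(badSide, collapse = ", "))
  df$category <- if (nrow(df)) categoryOf(df$method, df$normalized) else character(0)
  df
}

#' @rdname readManifest
#' @param manifest data.frame with the manifest columns.
#' @export
writeManifest <- function(manifest, path) {
  missing <- setdiff(manifestColumns, names(manifest))
  if (length(missing))
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(manifest[, manifestColumns, drop = FALSE], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read the per-image results table
#'
#' One row per analyzed image: identifiers, the GSM and descriptive
#' statistics of the kidney region, one percentage column per brightness
#' band, and the normalization record when one was applied. All rows must
#' share one key set; numeric values are written with full precision
#' (well beyond 4 significant digits).
#'
#' @param rows a data.frame, or a list of named lists with identical names.
#' @param path output CSV path.
#' @return \code{writeResultsTable}: invisibly, \code{path}.
#' @export
writeResultsTable <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    if (!length(rows)) stop("writeResultsTable needs a data.frame for an empty table")
    keys <- lapply(rows, names)
    if (!all(vapply(keys, identical, logical(1), y = keys[[1L]])))
      stop("heterogeneous result rows: all rows must share one key set")
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  if (!file.exists(path)) stop("cannot read results table: file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
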