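# Minimal uncompressed Windows BMP codec (8-bit palette and 24-bit RGB).
# Written here because the canonical on-disk format for this tool is BMP
# and no other supported read path exists for it; only the features the
# tool needs (BI_RGB, bottom-up or top-down rows) are implemented.

rdU16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
rdU32 <- function(raw, at) {
  sum(as.numeric(raw[at + 0:3]) * c(1, 256, 65536, 16777216))
}
rdI32 <- function(raw, at) {
  u <- rdU32(raw, at)
  if (u >= 2147483648) u - 4294967296 else u
}
wrU16 <- function(x) as.raw(c(x %% 256, x %/% 256))
wrU32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

# Rec.601 luma, rounded half away from zero; maps gray triples to themselves.
lumaRec601 <- function(r, g, b) roundHalfAway(0.299 * r + 0.587 * g + 0.114 * b)

#' Read a grayscale BMP image
#'
#' Reads an uncompressed Windows bitmap. 8-bit files are read through their
#' palette (an identity gray palette returns the stored indices unchanged;
#' color palettes are collapsed by Rec.601 luma). 24-bit files are converted
#' per pixel by the Rec.601 weighting 0.299 R + 0.587 G + 0.114 B, rounded
#' half away from zero. Both bottom-up and top-down row orders are handled.
#'
#' @param path path to a \code{.bmp} file.
#' @return A \linkS4class{GrayImage}; \code{sourceId} is set to the file name.
#' @seealso [writeGrayBMP()], [readGrayImage()] for courtesy PNG input.
#' @export
readGrayBMP <- function(path) {
  if (!file.exists(path)) stop("cannot read BMP: file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file (missing 'BM' signature): ", path)
  dataOffset <- rdU32(raw, 11L)
  hdrSize <- rdU32(raw, 15L)
  if (hdrSize < 40) stop("unsupported BMP header (need BITMAPINFOHEADER or later)")
  width <- rdI32(raw, 19L)
  heightRaw <- rdI32(raw, 23L)
  topDown <- heightRaw < 0
  height <- abs(heightRaw)
  bitCount <- rdU16(raw, 29L)
  compression <- rdU32(raw, 31L)
  if (compression != 0) stop("unsupported BMP compression mode ", compression)
  if (!bitCount %in% c(8L, 24L))
    stop("unsupported BMP bit depth: ", bitCount, " (only 8-bit and 24-bit are read)")
  if (width < 1 || height < 1) stop("degenerate BMP dimensions")

  bytesPerPx <- bitCount %/% 8L
  rowBytes <- ((width * bytesPerPx + 3L) %/% 4L) * 4L
  need <- dataOffset + rowBytes * height
  if (length(raw) < need) stop("truncated BMP pixel data")

  if (bitCount == 8L) {
    nPal <- rdU32(raw, 47L)
    if (nPal == 0) nPal <- 256
    palRaw <- raw[(14L + hdrSize + 1L):(14L + hdrSize + 4L * nPal)]
    pal <- matrix(as.integer(palRaw), ncol = 4L, byrow = TRUE)  # B, G, R, 0
    lut <- as.integer(lumaRec601(pal[, 3L], pal[, 2L], pal[, 1L]))
    if (length(lut) < 256L) lut <- c(lut, seq.int(length(lut), 255L))
  }

  px <- matrix(0L, nrow = height, ncol = width)
  rowIdx <- if (topDown) seq_len(height) else rev(seq_len(height))
  base <- dataOffset
  for (i in seq_len(height)) {
    row <- raw[(base + 1L):(base + rowBytes)]
    if (bitCount == 8L) {
      px[rowIdx[i], ] <- lut[as.integer(row[seq_len(width)]) + 1L]
    } else {
      v <- as.integer(row[seq_len(3L * width)])
      b <- v[seq(1L, by = 3L, length.out = width)]
      g <- v[seq(2L, by = 3L, length.out = width)]
      r <- v[seq(3L, by = 3L, length.out = width)]
      px[rowIdx[i], ] <- as.integer(lumaRec601(r, g, b))
    }
    base <- base + rowBytes
  }
  GrayImage(px, sourceId = basename(path))
}

#' Write a GrayImage as an 8-bit grayscale BMP
#'
#' Writes an uncompressed 8-bit BMP with an identity gray palette, so that
#' \code{readGrayBMP(writeGrayBMP(x))} reproduces \code{x} exactly.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeGrayBMP <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  px <- image@pixels
  w <- ncol(px); h <- nrow(px)
  rowBytes <- ((w + 3L) %/% 4L) * 4L
  dataOffset <- 14L + 40L + 1024L
  fileSize <- dataOffset + rowBytes * h
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))  # B G R 0 per entry
  body <- raw(rowBytes * h)
  pad <- rowBytes - w
  # bottom-up rows
  rows <- lapply(rev(seq_len(h)), function(y) {
    c(as.raw(px[y, ]), raw(pad))
  })
  body <- unlist(rows, use.names = FALSE)
  header <- c(charToRaw("BM"), wrU32(fileSize), wrU16(0), wrU16(0),
              wrU32(dataOffset),
              wrU32(40), wrU32(w), wrU32(h), wrU16(1), wrU16(8),
              wrU32(0), wrU32(rowBytes * h), wrU32(2835), wrU32(2835),
              wrU32(256), wrU32(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, pal, body), con)
  invisible(path)
}

#' Write an RGB raster as a 24-bit BMP
#'
#' Used to export pseudocolor renderings.
#'
#' @param rgb integer array of dim (height, width, 3), values in \[0, 255\],
#'   channels in R, G, B order.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeColorBMP <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  rowBytes <- ((3L * w + 3L) %/% 4L) * 4L
  dataOffset <- 54L
  pad <- rowBytes - 3L * w
  rows <- lapply(rev(seq_len(h)), function(y) {
    inter <- rbind(rgb[y, , 3L], rgb[y, , 2L], rgb[y, , 1L])  # BGR interleave
    c(as.raw(as.integer(inter)), raw(pad))
  })
  body <- unlist(rows, use.names = FALSE)
  header <- c(charToRaw("BM"), wrU32(dataOffset + rowBytes * h), wrU16(0),
              wrU16(0), wrU32(dataOffset),
              wrU32(40), wrU32(w), wrU32(h), wrU16(1), wrU16(24),
              wrU32(0), wrU32(rowBytes * h), wrU32(2835), wrU32(2835),
              wrU32(0), wrU32(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}
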