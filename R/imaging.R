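#' @include augment.R
NULL

#' Cropping-style presets for coherence plots
#'
#' Three named presets crop the coherence plot around the impulse:
#' \itemize{
#'   \item horizontal: 0.1-0.35 s x 4-8 Hz, tiles left-to-right;
#'   \item vertical: 0.1-0.2 s x 0-12 Hz, tiles top-to-bottom;
#'   \item subtotal: 0.1-0.3 s x 0-125 Hz, tiles left-to-right.
#' }
#'
#' @param name preset name.
#' @return a \linkS4class{CropStyle}.
#' @export
cropStyle <- function(name = c("horizontal", "vertical", "subtotal")) {
  name <- match.arg(name)
  switch(name,
    horizontal = new("CropStyle", name = "horizontal",
                     timeWindow = c(0.1, 0.35), freqWindow = c(4, 8),
                     tiling = "left-to-right"),
    vertical   = new("CropStyle", name = "vertical",
                     timeWindow = c(0.1, 0.2), freqWindow = c(0, 12),
                     tiling = "top-to-bottom"),
    subtotal   = new("CropStyle", name = "subtotal",
                     timeWindow = c(0.1, 0.3), freqWindow = c(0, 125),
                     tiling = "left-to-right"))
}

# fixed perceptually-uniform colormap: 256-level viridis lookup; a bijection
# on the quantized [0,1] coherence scale
coherencePalette <- local({
  pal <- NULL
  function() {
    if (is.null(pal)) {
      cols <- grDevices::hcl.colors(256, "viridis")
      pal <<- t(grDevices::col2rgb(cols) / 255)
    }
    pal
  }
})

#' Decode a rendered coherence color back to its value
#'
#' Inverts the fixed colormap by nearest palette entry; exact to the 1/255
#' quantization for colors produced by \code{\link{renderCoherenceRaster}}.
#'
#' @param rgb numeric length-3 RGB in [0, 1].
#' @return coherence value in [0, 1].
#' @export
decodeCoherenceColor <- function(rgb) {
  pal <- coherencePalette()
  d2 <- colSums((t(pal) - rgb)^2)
  (which.min(d2) - 1) / 255
}

#' Render a coherence map as a cropped power-spectrum raster
#'
#' Heatmap of MSWC with a fixed color scale on [0, 1], linear time axis and
#' log2 frequency axis, without axes or annotations. Pixel values are
#' bilinear samples of the coherence matrix in (time, log2 f) coordinates.
#' Frequencies the grid cannot resolve (above the top grid frequency, or
#' any part of a window reaching below the grid floor) are rendered as the
#' zero-coherence color; for windows whose lower frequency bound is 0 the
#' log axis floor is the lowest resolvable grid frequency.
#'
#' @param map a \linkS4class{CoherenceMap}.
#' @param style a \linkS4class{CropStyle} (or preset name).
#' @param res square raster edge in pixels; default 224.
#' @return numeric array res x res x 3, RGB in [0, 1]; row 1 is the top of
#'   the image (highest frequency), column 1 the window start.
#' @export
renderCoherenceRaster <- function(map, style, res = 224L) {
  if (is.character(style)) style <- cropStyle(style)
  freqs <- map@grid@frequencies                  # decreasing
  fLoGrid <- min(freqs); fHiGrid <- max(freqs)
  tw <- style@timeWindow
  fw <- style@freqWindow
  fLo <- max(fw[1], fLoGrid)
  fHi <- fw[2]
  stopIfNot(fLo < fHi && tw[1] < max(map@times) && tw[2] > min(map@times),
            "crop window does not overlap the resolvable region")
  res <- as.integer(res)
  # pixel centers in data coordinates
  px <- (seq_len(res) - 0.5) / res
  tPix <- tw[1] + px * diff(tw)
  lfPix <- log2(fHi) - (seq_len(res) - 0.5) / res * (log2(fHi) - log2(fLo))
  # fractional indices into the matrix: rows uniform in log2(f), cols in t
  lf <- log2(freqs)
  rowIdx <- 1 + (lf[1] - lfPix) / (lf[1] - lf[2])  # geometric grid: constant step
  dtm <- map@times[2] - map@times[1]               # times are uniform
  colIdx <- 1 + (tPix - map@times[1]) / dtm
  vals <- bilinearSample(map@mswc, rowIdx, colIdx)
  vals[!is.finite(vals)] <- 0
  vals <- pmin(pmax(vals, 0), 1)
  pal <- coherencePalette()
  idx <- round(vals * 255) + 1
  out <- array(0, c(res, res, 3))
  out[, , 1] <- matrix(pal[idx, 1], res, res)
  out[, , 2] <- matrix(pal[idx, 2], res, res)
  out[, , 3] <- matrix(pal[idx, 3], res, res)
  out
}

# bilinear sampling of matrix M at fractional (row, col) positions; the
# outer product of the row and column position vectors defines the raster.
# positions outside the matrix return NA (rendered as zero coherence)
bilinearSample <- function(M, rowIdx, colIdx) {
  nr <- nrow(M); nc <- ncol(M)
  r0 <- floor(rowIdx); c0 <- floor(colIdx)
  fr <- rowIdx - r0; fc <- colIdx - c0
  r0c <- pmin(pmax(r0, 1), nr); r1c <- pmin(r0c + 1, nr)
  c0c <- pmin(pmax(c0, 1), nc); c1c <- pmin(c0c + 1, nc)
  frm <- matrix(fr, length(rowIdx), length(colIdx))
  fcm <- matrix(fc, length(rowIdx), length(colIdx), byrow = TRUE)
  v <- M[r0c, c0c, drop = FALSE] * (1 - frm) * (1 - fcm) +
       M[r1c, c0c, drop = FALSE] * frm * (1 - fcm) +
       M[r0c, c1c, drop = FALSE] * (1 - frm) * fcm +
       M[r1c, c1c, drop = FALSE] * frm * fcm
  bad <- outer(rowIdx < 0.5 | rowIdx > nr + 0.5,
               colIdx < 0.5 | colIdx > nc + 0.5, `|`)
  v[bad] <- NA_real_
  v
}

#' Crop three SCC coherence maps and tile them into one patient image
#'
#' Renders each SCC map in the given style at a per-tile resolution of
#' 224 x 224 (so the three crops carry equal pixel weight), tiles them in
#' the fixed order horizontal, anterior, posterior (left-to-right or
#' top-to-bottom per the style), and resizes the tiled image to
#' \code{outputSize} with bilinear interpolation.
#'
#' @param maps named list of three \linkS4class{CoherenceMap}s with names
#'   horizontal, anterior, posterior.
#' @param style a \linkS4class{CropStyle} or preset name.
#' @param outputSize final square edge in pixels; default 224.
#' @param patientId identifier stored in the image.
#' @param tileRes per-tile raster resolution; default 224.
#' @return a \linkS4class{TiledImage}.
#' @export
cropAndTile <- function(maps, style, outputSize = 224L, patientId = "",
                        tileRes = 224L) {
  if (is.character(style)) style <- cropStyle(style)
  stopIfNot(all(SCC_LEVELS %in% names(maps)),
            "maps must contain horizontal, anterior and posterior entries")
  tiles <- lapply(SCC_LEVELS, function(scc)
    renderCoherenceRaster(maps[[scc]], style, res = tileRes))
  joined <- joinTiles(tiles, style@tiling)
  pix <- resizeBilinear(joined, as.integer(outputSize), as.integer(outputSize))
  new("TiledImage", pixels = pix, style = style,
      patientId = as.character(patientId), sccOrder = SCC_LEVELS)
}

joinTiles <- function(tiles, tiling) {
  if (tiling == "left-to-right") {
    r <- do.call(cbind, lapply(tiles, function(t) t[, , 1]))
    g <- do.call(cbind, lapply(tiles, function(t) t[, , 2]))
    b <- do.call(cbind, lapply(tiles, function(t) t[, , 3]))
  } else {
    r <- do.call(rbind, lapply(tiles, function(t) t[, , 1]))
    g <- do.call(rbind, lapply(tiles, function(t) t[, , 2]))
    b <- do.call(rbind, lapply(tiles, function(t) t[, , 3]))
  }
  out <- array(0, c(nrow(r), ncol(r), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

# bilinear resize of an H x W x 3 array via EBImage
resizeBilinear <- function(img, h, w) {
  if (dim(img)[1] == h && dim(img)[2] == w) return(img)
  # EBImage images are x (col) by y (row); transpose in and out
  e <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  r <- EBImage::resize(e, w = w, h = h, filter = "bilinear")
  out <- aperm(EBImage::imageData(r), c(2, 1, 3))
  pmin(pmax(out, 0), 1)
}

#' Write a tiled image as PNG
#'
#' @param image a \linkS4class{TiledImage}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTiledImage <- function(image, path) {
  png::writePNG(image@pixels, target = path)
  invisible(path)
}
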