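#' Calibrated intensity image
#'
#' A 2-D non-negative intensity raster with an explicit physical pixel size
#' and a channel label. Coordinates follow a 0-based convention: pixel
#' `(x, y)` occupies the unit square centred at column `x`, row `y`, with
#' `x = 0` the left-most column and `y = 0` the top row (matching how TIFF
#' readers return rasters). All physical quantities are `pixel_size` units
#' per pixel edge.
#'
#' @param pixels numeric matrix of intensities, rows = y, columns = x.
#' @param pixel_size physical length of one pixel edge (> 0).
#' @param unit unit of `pixel_size`, `"um"` or `"nm"`.
#' @param channel free-text channel label, e.g. `"mCherry::SP12"`.
#' @return object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size, unit = c("um", "nm"), channel = "") {
  unit <- match.arg(unit)
  cm_assert(is.matrix(pixels) && is.numeric(pixels), "image",
            "`pixels` must be a numeric matrix")
  cm_assert(nrow(pixels) >= 8 && ncol(pixels) >= 8, "image",
            "raster must be at least 8x8 pixels")
  cm_assert(all(is.finite(pixels)) && all(pixels >= 0), "image",
            "intensities must be finite and non-negative")
  cm_assert(is.numeric(pixel_size) && length(pixel_size) == 1 && pixel_size > 0,
            "image", "`pixel_size` must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         unit = unit, channel = as.character(channel)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %dx%d px, %.4g %s/px, channel \"%s\"\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, x$unit, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Load a calibrated image from TIFF or PNG
#'
#' Integer TIFFs (uint8/uint16) are read as raw counts; float TIFFs are read
#' as stored. PNG is read at its native bit depth and rescaled to integer
#' counts. Multi-page TIFFs require an explicit `page` selection.
#'
#' @param path readable TIFF (`.tif`/`.tiff`) or PNG file.
#' @param pixel_size,unit physical calibration, as in [calibrated_image()].
#' @param channel channel label attached to the image.
#' @param page 1-based page index for multi-page TIFFs (default first page;
#'   selecting a page from a single-page file is an error only if out of range).
#' @return a [calibrated_image()].
#' @export
load_image <- function(path, pixel_size, unit = c("um", "nm"), channel = "",
                       page = NULL) {
  unit <- match.arg(unit)
  cm_assert(file.exists(path), "io", sprintf("cannot read '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE),
                      error = function(e) cm_stop("io", conditionMessage(e)))
    if (length(pages) > 1 && is.null(page))
      cm_stop("dimension", sprintf(
        "'%s' has %d pages; select one with `page=`", path, length(pages)))
    if (is.null(page)) page <- 1L
    cm_assert(page >= 1 && page <= length(pages), "dimension",
              sprintf("page %d out of range (file has %d)", page, length(pages)))
    px <- pages[[page]]
  } else if (ext == "png") {
    px <- tryCatch(png::readPNG(path), error = function(e) cm_stop("io", conditionMessage(e)))
    if (length(dim(px)) == 2) px <- round(px * 65535)
  } else {
    cm_stop("io", sprintf("unsupported image format '.%s'", ext))
  }
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 1) px <- px[, , 1]
    else cm_stop("dimension", sprintf(
      "page is not 2-D (%s); extract a single channel first",
      paste(dim(px), collapse = "x")))
  }
  cm_log("load_image", path = path, pixel_size = pixel_size, unit = unit,
         channel = channel)
  calibrated_image(px, pixel_size, unit, channel)
}

#' Save a calibrated image as TIFF
#'
#' Default mode `"uint16"` stores integer counts 0..65535 losslessly, the
#' native representation of fluorescence data. Mode `"float"` writes 32-bit
#' floats but is restricted to values in \[0, 1\] by the underlying libtiff
#' wrapper; use it only for pre-normalised data.
#'
#' @param image a [calibrated_image()].
#' @param path output `.tif` path.
#' @param mode `"uint16"` (default) or `"float"`.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, mode = c("uint16", "float")) {
  mode <- match.arg(mode)
  px <- image$pixels
  if (mode == "uint16") {
    cm_assert(all(px == round(px)) && max(px) <= 65535, "io",
              "uint16 mode requires integer intensities in 0..65535")
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else {
    cm_assert(max(px) <= 1, "io", "float mode requires intensities in [0, 1]")
    suppressWarnings(tiff::writeTIFF(px, path, bits.per.sample = 32L))
  }
  invisible(path)
}

#' Pixel size from a marked scale bar
#'
#' Calibration by marking a known physical length across a run of pixels,
#' e.g. 11 consecutive pixels spanning 100 nm gives 100/11 nm per pixel.
#'
#' @param n_pixels number of pixels spanned (>= 1).
#' @param physical_length physical length of the marked span (> 0).
#' @return length per pixel, in the units of `physical_length`.
#' @export
pixel_size_from_scalebar <- function(n_pixels, physical_length) {
  cm_assert(n_pixels >= 1, "calibration", "`n_pixels` must be >= 1")
  cm_assert(physical_length > 0, "calibration", "`physical_length` must be > 0")
  physical_length / n_pixels
}

#' Bilinear interpolation at fractional pixel coordinates
#'
#' @param pixels intensity matrix (rows = y, cols = x).
#' @param x,y 0-based fractional coordinates; must lie within
#'   `[0, ncol-1] x [0, nrow-1]`.
#' @return interpolated intensities.
#' @noRd
bilinear <- function(pixels, x, y) {
  ny <- nrow(pixels); nx <- ncol(pixels)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- pixels[cbind(y0 + 1, x0 + 1)]
  i01 <- pixels[cbind(y0 + 1, x0 + 2)]
  i10 <- pixels[cbind(y0 + 2, x0 + 1)]
  i11 <- pixels[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}
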