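new_threshold_mask <- function(mask, lower, upper, rule, image) {
  cm_assert(lower <= upper, "threshold_inversion",
            sprintf("lower threshold (%.4g) exceeds upper (%.4g)", lower, upper))
  structure(
    list(mask = mask, lower = lower, upper = upper, rule = rule,
         pixel_size = image$pixel_size, unit = image$unit),
    class = "threshold_mask"
  )
}

#' @export
print.threshold_mask <- function(x, ...) {
  cat(sprintf("<threshold_mask> rule \"%s\", [%.4g, %.4g], %d px selected\n",
              x$rule, x$lower, x$upper, sum(x$mask)))
  invisible(x)
}

# Stats over an arbitrary logical pixel selection.
stats_of_selection <- function(image, sel, what) {
  vals <- image$pixels[sel]
  cm_assert(length(vals) >= 1, "empty_region", sprintf("%s region is empty", what))
  list(mean = mean(vals), min = min(vals), max = max(vals), n = length(vals))
}

#' Threshold mask of a torus-traced ring signal
#'
#' The ring is roughly traced as a torus: an outer polygon minus an inner
#' one. The lower threshold is `(mean + min) / 2` of the torus region's
#' intensities, the upper threshold is the region maximum ("Maxthr"), and
#' the mask keeps torus pixels whose intensity lies in `[lower, upper]`
#' (both ends inclusive, so a uniform region is fully selected).
#'
#' @param image a [calibrated_image()].
#' @param outer,inner [polygon_roi()]s; the torus is `outer` minus `inner`.
#' @return a `threshold_mask` (rule `"torus_mean_min"`).
#' @export
torus_threshold <- function(image, outer, inner) {
  sel <- roi_mask(outer, dim(image$pixels)) & !roi_mask(inner, dim(image$pixels))
  st <- stats_of_selection(image, sel, "torus")
  lower <- (st$mean + st$min) / 2
  mask <- sel & image$pixels >= lower & image$pixels <= st$max
  cm_log("torus_threshold", outer = roi_hash(outer), inner = roi_hash(inner),
         lower = lower, upper = st$max)
  new_threshold_mask(mask, lower, st$max, "torus_mean_min", image)
}

#' Threshold mask locating a ring's inner edge from a traced void
#'
#' Variant used for the tubulin-ring inner edge: the void is roughly traced
#' (a polygon extending slightly into the ring), the lower threshold is
#' `(mean + max) / 2` of that region and the upper is the region maximum, so
#' only the bright inner rim of the ring survives inside the trace.
#'
#' @param image a [calibrated_image()].
#' @param void_roi a [polygon_roi()] over the ring void, overlapping the
#'   ring's inner rim on all sides.
#' @return a `threshold_mask` (rule `"void_mean_max"`).
#' @export
void_threshold <- function(image, void_roi) {
  sel <- roi_mask(void_roi, dim(image$pixels))
  st <- stats_of_selection(image, sel, "void trace")
  lower <- (st$mean + st$max) / 2
  mask <- sel & image$pixels >= lower & image$pixels <= st$max
  cm_log("void_threshold", roi = roi_hash(void_roi), lower = lower, upper = st$max)
  new_threshold_mask(mask, lower, st$max, "void_mean_max", image)
}

#' Threshold mask of the PCM ("wand tool" selection)
#'
#' The lower threshold is the *sum* of the mean and maximum intensity of a
#' background region outside the PCM; the upper threshold is the image
#' maximum. Of the pixels passing the threshold, the connected component
#' (8-connected) containing the seed — by default the brightest pixel — is
#' the PCM mask, emulating a wand-tool click on the object.
#'
#' @param image a [calibrated_image()].
#' @param background a [polygon_roi()] outside the PCM.
#' @param seed_point optional `c(x, y)` seed; defaults to the global
#'   intensity maximum.
#' @return a `threshold_mask` (rule `"background_mean_plus_max"`).
#' @export
pcm_threshold <- function(image, background, seed_point = NULL) {
  bg <- region_stats(image, background)
  lower <- bg$mean + bg$max
  upper <- max(image$pixels)
  cm_assert(lower <= upper, "threshold_inversion",
            sprintf(paste0("background-derived lower threshold (%.4g) exceeds the ",
                           "image maximum (%.4g): background brighter than object"),
                    lower, upper))
  cand <- image$pixels >= lower & image$pixels <= upper
  if (is.null(seed_point)) {
    i <- which.max(image$pixels)
    seed_point <- c((i - 1) %/% nrow(image$pixels),
                    (i - 1) %% nrow(image$pixels))
  }
  mask <- component_at(cand, seed_point, connectivity = 8)
  cm_log("pcm_threshold", background = roi_hash(background), lower = lower,
         upper = upper, seed = seed_point)
  new_threshold_mask(mask, lower, upper, "background_mean_plus_max", image)
}

#' Void area enclosed by a thresholded ring
#'
#' The void is the connected region of non-ring pixels containing the
#' declared centre, bounded by the inner edge of the thresholded ring.
#' Background connectivity is 4-connected (ring foreground is treated as
#' 8-connected), so a closed diagonal chain of ring pixels still confines the
#' void. If the region containing the centre reaches the raster border the
#' ring is not closed and an error is raised rather than silently filling.
#'
#' @param mask a `threshold_mask` or logical matrix (ring = `TRUE`).
#' @param center `c(x, y)` point inside the void, 0-based pixel coordinates.
#' @param pixel_size required when `mask` is a bare matrix.
#' @return void area in physical units^2.
#' @export
void_area <- function(mask, center, pixel_size = NULL) {
  if (inherits(mask, "threshold_mask")) {
    pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  cm_assert(!is.null(pixel_size), "argument",
            "`pixel_size` is required with a bare mask")
  void <- component_at(!mask, center, connectivity = 4)
  cm_assert(!touches_border(void), "open_ring",
            "ring is not closed around the centre: the void reaches the raster border",
            data = list(void_px = sum(void)))
  cm_log("void_area", area_px = sum(void), pixel_size = pixel_size)
  sum(void) * pixel_size^2
}

#' Area and raw intensity under a mask
#'
#' @param mask a `threshold_mask` or logical matrix.
#' @param image the [calibrated_image()] to read intensities from (for
#'   multi-channel data this may be a different, co-registered channel than
#'   the one that produced the mask).
#' @return object of class `area_intensity` with `area` (physical units^2),
#'   `total_intensity` (summed raw pixel values, "RawInt") and
#'   `density = total_intensity / area`.
#' @export
area_intensity <- function(mask, image) {
  if (inherits(mask, "threshold_mask")) mask <- mask$mask
  n <- sum(mask)
  cm_assert(n >= 1, "empty_region", "mask selects no pixels")
  area <- n * image$pixel_size^2
  total <- sum(image$pixels[mask])
  structure(list(area = area, total_intensity = total, density = total / area,
                 area_px = n, unit = image$unit),
            class = "area_intensity")
}

#' @export
print.area_intensity <- function(x, ...) {
  cat(sprintf("<area_intensity> area %.4g %s^2, total %.4g, density %.4g\n",
              x$area, x$unit, x$total_intensity, x$density))
  invisible(x)
}

#' Intensity of a second channel confined to a traced outline
#'
#' For proteins present both at the centrosome and elsewhere (e.g. tubulin in
#' the spindle), the total intensity is confined to the region enclosed by an
#' outline traced on another channel: the outline polygon from channel A is
#' applied to the co-registered channel B.
#'
#' @param outline a [polygon_roi()] (e.g. the traced outer edge of the
#'   membrane signal).
#' @param other the co-registered [calibrated_image()] to measure.
#' @return an `area_intensity` over the pixels inside the outline.
#' @export
intensity_within_outline <- function(outline, other) {
  v <- outline$vertices
  ny <- nrow(other$pixels); nx <- ncol(other$pixels)
  cm_assert(all(v[, 1] >= 0 & v[, 1] <= nx - 1 & v[, 2] >= 0 & v[, 2] <= ny - 1),
            "geometry", "outline extends outside the raster")
  m <- roi_mask(outline, dim(other$pixels))
  cm_assert(any(m), "empty_region", "outline encloses no pixel centres")
  cm_log("intensity_within_outline", roi = roi_hash(outline),
         channel = other$channel)
  area_intensity(m, other)
}

#' Peri-centrosomal microtubule ring area with spindle exclusion
#'
#' The tubulin ring is thresholded exactly as in [torus_threshold()]; pixels
#' inside the spindle-exclusion polygon are removed before measurement so
#' spindle signal is never picked up. The returned area is the area enclosed
#' by the outer edge of the surviving mask, reconstructed across any excluded
#' wedge by the convex closure of the surviving pixels (pixel centres inside
#' the convex hull are counted).
#'
#' @param image a [calibrated_image()] of the tubulin channel.
#' @param outer,inner torus trace as in [torus_threshold()].
#' @param spindle_exclusion optional [polygon_roi()] to remove, or `NULL`.
#' @return list with `area` (physical units^2), the surviving `mask` and the
#'   filled outer mask `outer_mask`.
#' @export
mt_ring_area <- function(image, outer, inner, spindle_exclusion = NULL) {
  tm <- torus_threshold(image, outer, inner)
  mask <- tm$mask
  if (!is.null(spindle_exclusion))
    mask <- mask & !roi_mask(spindle_exclusion, dim(image$pixels))
  cm_assert(any(mask), "empty_region",
            "no ring signal survives thresholding and exclusion")
  idx <- which(mask)
  xs <- (idx - 1) %/% nrow(mask)
  ys <- (idx - 1) %% nrow(mask)
  hull <- grDevices::chull(xs, ys)
  if (length(hull) < 3) cm_stop("geometry", "surviving mask is degenerate (collinear)")
  hull_roi <- polygon_roi(cbind(xs[hull], ys[hull]))
  outer_mask <- roi_mask(hull_roi, dim(mask))
  cm_log("mt_ring_area", area_px = sum(outer_mask))
  list(area = sum(outer_mask) * image$pixel_size^2,
       mask = mask, outer_mask = outer_mask)
}
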