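#' Polygonal region of interest
#'
#' Replaces the manual freehand tracing step: regions arrive as simple
#' polygons in 0-based pixel coordinates. Membership of a pixel is decided at
#' its centre, boundary inclusive, so clockwise and counter-clockwise
#' orderings of the same vertices select the same pixels.
#'
#' @param vertices n x 2 numeric matrix (or list of `c(x, y)` pairs) of
#'   ordered polygon vertices, 0-based pixel coordinates.
#' @param kind one of `"torus_outer"`, `"torus_inner"`, `"background"`,
#'   `"spindle_exclusion"`, `"freehand"`.
#' @return object of class `polygon_roi`.
#' @export
polygon_roi <- function(vertices,
                        kind = c("freehand", "torus_outer", "torus_inner",
                                 "background", "spindle_exclusion")) {
  kind <- match.arg(kind)
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  cm_assert(is.numeric(vertices) && ncol(vertices) == 2 && nrow(vertices) >= 3,
            "roi", "a polygon needs >= 3 (x, y) vertices")
  cm_assert(all(is.finite(vertices)), "roi", "vertices must be finite")
  cm_assert(!polygon_self_intersects(vertices), "roi",
            "polygon must be simple (non-self-intersecting)")
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices, kind = kind), class = "polygon_roi")
}

#' @export
print.polygon_roi <- function(x, ...) {
  cat(sprintf("<polygon_roi> kind \"%s\", %d vertices\n", x$kind, nrow(x$vertices)))
  invisible(x)
}

# Segment-intersection scan over non-adjacent edge pairs; O(n^2) but ROIs are
# small. Shared endpoints between adjacent edges are not intersections.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    for (j in js) {
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross2(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross2(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross2(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross2(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) return(TRUE)
    }
  }
  FALSE
}

#' Write / read ROIs as JSON
#'
#' One ROI per object: `{"kind": ..., "vertices": [[x, y], ...]}`. A file may
#' hold a single ROI object or a JSON array of them. Vertices round-trip
#' bit-exactly (written at full precision).
#'
#' @param roi a [polygon_roi()] or list of them.
#' @param path JSON file path.
#' @return `write_roi_json`: `path` invisibly; `read_roi_json`: a
#'   [polygon_roi()] (or list of them if the file holds an array).
#' @export
write_roi_json <- function(roi, path) {
  as_entry <- function(r) list(kind = r$kind, vertices = unname(r$vertices))
  payload <- if (inherits(roi, "polygon_roi")) as_entry(roi) else lapply(roi, as_entry)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  cm_assert(file.exists(path), "io", sprintf("cannot read '%s'", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_entry <- function(e) polygon_roi(e$vertices, kind = e$kind)
  if (!is.data.frame(obj) && length(obj$kind) == 1) from_entry(obj) else lapply(
    seq_len(if (is.data.frame(obj)) nrow(obj) else length(obj)),
    function(i) from_entry(if (is.data.frame(obj)) list(
      kind = obj$kind[[i]], vertices = obj$vertices[[i]]) else obj[[i]])
  )
}

# Stable content hash of an ROI for provenance logging.
roi_hash <- function(roi) {
  s <- paste(roi$kind, paste(sprintf("%.17g", t(roi$vertices)), collapse = ","))
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  sprintf("%08x", h)
}

#' Which pixel centres fall inside a polygon
#'
#' @param roi a [polygon_roi()].
#' @param dim_img `c(nrow, ncol)` of the raster.
#' @return logical matrix of the raster's dimensions; `TRUE` where the pixel
#'   centre is inside or on the polygon boundary.
#' @export
roi_mask <- function(roi, dim_img) {
  ny <- dim_img[1]; nx <- dim_img[2]
  v <- roi$vertices
  # restrict the point-in-polygon test to the bounding box
  xr <- max(0, floor(min(v[, 1]))):min(nx - 1, ceiling(max(v[, 1])))
  yr <- max(0, floor(min(v[, 2]))):min(ny - 1, ceiling(max(v[, 2])))
  m <- matrix(FALSE, ny, nx)
  if (length(xr) == 0 || length(yr) == 0) return(m)
  g <- expand.grid(x = xr, y = yr)
  inside <- pracma::inpolygon(g$x, g$y, v[, 1], v[, 2], boundary = TRUE)
  m[cbind(g$y + 1, g$x + 1)] <- inside
  m
}

#' Region statistics of an ROI
#'
#' Mean, minimum and maximum intensity plus pixel and physical area of the
#' pixels whose centres fall inside the polygon. These are the ingredients of
#' the thresholding formulas: the torus rule uses `(mean + min) / 2` as the
#' lower threshold and the region maximum ("Maxthr") as the upper.
#'
#' @param image a [calibrated_image()].
#' @param roi a [polygon_roi()]; all vertices must lie within the raster.
#' @return object of class `region_stats` with fields `mean`, `min`, `max`,
#'   `area_px`, `area_units` (= `area_px * pixel_size^2`).
#' @export
region_stats <- function(image, roi) {
  v <- roi$vertices
  ny <- nrow(image$pixels); nx <- ncol(image$pixels)
  cm_assert(all(v[, 1] >= 0 & v[, 1] <= nx - 1 & v[, 2] >= 0 & v[, 2] <= ny - 1),
            "geometry", "ROI vertices must lie inside the raster")
  m <- roi_mask(roi, dim(image$pixels))
  vals <- image$pixels[m]
  cm_assert(length(vals) >= 1, "empty_region",
            "ROI encloses no pixel centres")
  cm_log("region_stats", roi = roi_hash(roi), channel = image$channel)
  structure(
    list(mean = mean(vals), min = min(vals), max = max(vals),
         area_px = length(vals),
         area_units = length(vals) * image$pixel_size^2,
         unit = image$unit),
    class = "region_stats"
  )
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("<region_stats> mean %.4g, min %.4g, max %.4g; %d px = %.4g %s^2\n",
              x$mean, x$min, x$max, x$area_px, x$area_units, x$unit))
  invisible(x)
}

#' Regular-polygon approximation of a circle, in pixel coordinates
#'
#' Convenience for building circular ROIs around a known centre (used by the
#' synthetic-scene generators and in tests).
#'
#' @param center `c(x, y)` in 0-based pixel coordinates.
#' @param radius_px radius in pixels.
#' @param n number of vertices.
#' @param kind passed to [polygon_roi()].
#' @return a [polygon_roi()].
#' @export
circle_roi <- function(center, radius_px, n = 72, kind = "freehand") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  polygon_roi(cbind(center[1] + radius_px * cos(th),
                    center[2] + radius_px * sin(th)), kind = kind)
}
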