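#' Segmented membrane panel
#'
#' A binary *en face* view of the reticulum membrane, as produced by
#' projecting a segmented FIB-SEM volume: membrane pixels are foreground,
#' openings are background. Side and mitotic-phase labels are metadata
#' carried through to reports; they play no role in the computation.
#'
#' @param mask logical matrix, membrane = `TRUE`.
#' @param pixel_size nm per pixel edge.
#' @param side `"cortical"` or `"pronuclear"`.
#' @param phase `"prometaphase"` or `"metaphase"`.
#' @return object of class `membrane_panel`.
#' @export
membrane_panel <- function(mask, pixel_size,
                           side = c("cortical", "pronuclear"),
                           phase = c("prometaphase", "metaphase")) {
  side <- match.arg(side); phase <- match.arg(phase)
  if (is.numeric(mask)) mask <- mask > 0.5
  cm_assert(is.matrix(mask) && is.logical(mask), "panel",
            "`mask` must be a logical matrix")
  cm_assert(pixel_size > 0, "panel", "`pixel_size` must be > 0")
  cm_assert(any(mask) && !all(mask), "degenerate_panel",
            "panel must contain both membrane and opening pixels")
  structure(list(mask = mask, pixel_size = pixel_size, side = side,
                 phase = phase),
            class = "membrane_panel")
}

#' Load a membrane panel from a binary PNG or TIFF
#'
#' @param path image file; pixels above half of the value range count as
#'   membrane.
#' @param pixel_size nm per pixel (e.g. from [pixel_size_from_scalebar()]).
#' @param side,phase metadata labels, see [membrane_panel()].
#' @return a [membrane_panel()].
#' @export
load_panel <- function(path, pixel_size, side = "cortical",
                       phase = "prometaphase") {
  img <- load_image(path, pixel_size, unit = "nm")
  membrane_panel(img$pixels > max(img$pixels) / 2, pixel_size, side, phase)
}

new_hole_set <- function(areas, panel_area, pixel_size, meta = list()) {
  cm_assert(all(areas > 0), "holes", "hole areas must be positive")
  cm_assert(sum(areas) <= panel_area + 1e-9, "holes",
            "total hole area exceeds the panel area")
  structure(list(areas = as.numeric(areas), panel_area = panel_area,
                 open_fraction = 100 * sum(areas) / panel_area,
                 pixel_size = pixel_size, meta = meta),
            class = "hole_set")
}

#' @export
print.hole_set <- function(x, ...) {
  cat(sprintf("<hole_set> %d holes, open fraction %.3g%% of %.4g nm^2\n",
              length(x$areas), x$open_fraction, x$panel_area))
  invisible(x)
}

#' Detect and measure membrane holes
#'
#' Holes are 4-connected components of the open (background) phase; the
#' membrane itself is treated as 8-connected, the complement of the
#' fluorescence-void convention, so diagonal membrane chains never leak two
#' holes into one. With `border_policy = "exclude"` (default) components
#' touching the raster border are dropped: their true extent is unknown in a
#' cropped panel. No minimum-size floor is applied — single-pixel holes are
#' retained so the binned distribution sees everything below the passability
#' cutoff.
#'
#' @param panel a [membrane_panel()].
#' @param border_policy `"exclude"` or `"include"` border-touching holes.
#' @return a `hole_set`: per-hole `areas` (nm^2), `panel_area` (nm^2) and
#'   `open_fraction` (percent).
#' @export
extract_holes <- function(panel, border_policy = c("exclude", "include")) {
  border_policy <- match.arg(border_policy)
  holes <- !panel$mask
  lab <- label_components(holes, connectivity = 4)
  n_lab <- max(lab)
  keep <- rep(TRUE, n_lab)
  if (border_policy == "exclude" && n_lab > 0) {
    border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep[border_labs[border_labs > 0]] <- FALSE
  }
  areas <- if (n_lab == 0) numeric(0) else {
    counts <- tabulate(lab[lab > 0], nbins = n_lab)
    counts[keep & counts > 0] * panel$pixel_size^2
  }
  panel_area <- length(panel$mask) * panel$pixel_size^2
  cm_log("extract_holes", n = length(areas), border_policy = border_policy)
  new_hole_set(areas, panel_area, panel$pixel_size,
               meta = list(side = panel$side, phase = panel$phase))
}

#' Smallest hole a microtubule can pass through
#'
#' A microtubule of diameter `mt_diameter` needs an opening of at least
#' `pi * (mt_diameter / 2)^2`; for the canonical 25 nm diameter this is
#' 490.87 nm^2, conventionally quoted truncated to 490 nm^2.
#'
#' @param mt_diameter microtubule diameter in nm (default 25).
#' @param as_printed truncate the result to an integer nm^2.
#' @return area in nm^2.
#' @export
min_passable_area <- function(mt_diameter = 25, as_printed = FALSE) {
  cm_assert(mt_diameter > 0, "argument", "`mt_diameter` must be > 0")
  a <- pi * (mt_diameter / 2)^2
  if (as_printed) trunc(a) else a
}

#' Holes large enough to pass a microtubule
#'
#' @param holes a `hole_set`.
#' @param cutoff minimum area (nm^2), e.g. [min_passable_area()].
#' @return a `hole_set` restricted to holes with `area >= cutoff`; the open
#'   fraction is recomputed over the same panel area.
#' @export
passable_holes <- function(holes, cutoff = min_passable_area()) {
  cm_assert(cutoff >= 0, "argument", "`cutoff` must be >= 0")
  new_hole_set(holes$areas[holes$areas >= cutoff], holes$panel_area,
               holes$pixel_size, holes$meta)
}

#' Hole-size bin edges (nm^2)
#'
#' 500 nm^2 bins up to 1000 nm^2, then 1000 nm^2 bins up to 10000 nm^2, with
#' an overflow bin above 10000 nm^2. Bins are right-closed: (0, 500],
#' (500, 1000], (1000, 2000], ..., (9000, 10000], (10000, Inf).
#'
#' @return numeric vector of bin edges including 0 and `Inf`.
#' @export
hole_bin_edges <- function() c(0, 500, 1000, seq(2000, 10000, by = 1000), Inf)

#' Binned hole-size distribution
#'
#' @param holes a non-empty `hole_set`.
#' @return object of class `binned_distribution`: a data frame with one row
#'   per bin (`bin`, `lower`, `upper`, `count`, `counts_percent`,
#'   `area_nm2`, `area_percent`). Both percentage columns sum to 100.
#' @export
bin_distribution <- function(holes) {
  cm_assert(length(holes$areas) >= 1, "empty_set",
            "cannot bin an empty hole set")
  edges <- hole_bin_edges()
  idx <- cut(holes$areas, breaks = edges, right = TRUE, labels = FALSE)
  k <- length(edges) - 1
  count <- tabulate(idx, nbins = k)
  area <- vapply(seq_len(k), function(b) sum(holes$areas[idx == b]), numeric(1))
  labels <- c(sprintf("(%g, %g]", edges[-c(k, k + 1)], edges[-c(1, k + 1)]),
              sprintf(">%g", edges[k]))
  out <- data.frame(
    bin = labels, lower = edges[-(k + 1)], upper = edges[-1],
    count = count, counts_percent = 100 * count / sum(count),
    area_nm2 = area, area_percent = 100 * area / sum(area)
  )
  class(out) <- c("binned_distribution", "data.frame")
  out
}

#' Viewing-angle check for en face panels
#'
#' A panel is usable only when viewed close to en face: the line from the
#' central fiducial to a fiducial at the image top/bottom edge must make an
#' angle of less than 30 degrees with the central plane.
#'
#' @param center_fiducial,edge_fiducial distinct 3-D points.
#' @param plane_normal non-zero 3-D normal of the central plane.
#' @param limit pass threshold in degrees (default 30).
#' @return list with `angle` (degrees in \[0, 90\]), `limit` and `pass`
#'   (`angle < limit`).
#' @export
viewing_angle <- function(center_fiducial, edge_fiducial, plane_normal,
                          limit = 30) {
  v <- as.numeric(edge_fiducial) - as.numeric(center_fiducial)
  cm_assert(sqrt(sum(v^2)) > 0, "geometry", "fiducials coincide")
  nrm <- as.numeric(plane_normal)
  cm_assert(sqrt(sum(nrm^2)) > 0, "geometry", "plane normal is zero")
  s <- abs(sum(v * nrm)) / (sqrt(sum(v^2)) * sqrt(sum(nrm^2)))
  angle <- asin(min(1, s)) * 180 / pi
  list(angle = angle, limit = limit, pass = angle < limit)
}
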