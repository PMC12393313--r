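#' Measure a tubulin ring with both width estimators
#'
#' Composes the full ring-width pipeline on one channel: the outer-edge area
#' (torus threshold + convex closure, [mt_ring_area()]), the inner void area
#' (void-trace threshold, [void_threshold()], then [void_area()] inside the
#' selected rim), the circle-equivalent width `R1 - R2`
#' ([ring_width_threshold()]), and the 90%-of-max line-scan width from two
#' perpendicular profiles ([ring_width_linescan()]).
#'
#' @param image tubulin-channel [calibrated_image()].
#' @param outer,inner torus trace polygons, as in [torus_threshold()].
#' @param void_roi void trace polygon, as in [void_threshold()].
#' @param center ring centre, 0-based pixel coordinates.
#' @param scan_length line-scan length, physical units (default: the image's
#'   shorter side minus a 2-pixel margin).
#' @param line_width line-scan averaging width, physical units.
#' @param angles two perpendicular scan angles, degrees.
#' @param spindle_exclusion optional exclusion polygon for the outer area.
#' @return a `ring_width` with both `width_threshold` and `width_linescan`
#'   filled in, plus `outer_area` and `void_area`.
#' @export
measure_ring_width <- function(image, outer, inner, void_roi, center,
                               scan_length = NULL,
                               line_width = image$pixel_size,
                               angles = c(0, 90), spindle_exclusion = NULL) {
  out <- mt_ring_area(image, outer, inner, spindle_exclusion)
  rim <- void_threshold(image, void_roi)
  v_area <- void_area(rim, center)
  thr <- ring_width_threshold(out$area, v_area)
  if (is.null(scan_length))
    scan_length <- (min(dim(image$pixels)) - 4) * image$pixel_size
  p1 <- line_scan(image, center, angles[1], scan_length, line_width)
  p2 <- line_scan(image, center, angles[2], scan_length, line_width)
  ls <- ring_width_linescan(p1, p2)
  structure(list(R1 = thr$R1, R2 = thr$R2,
                 width_threshold = thr$width_threshold,
                 peak_widths = ls$peak_widths,
                 width_linescan = ls$width_linescan,
                 outer_area = out$area, void_area = v_area,
                 unit = image$unit),
            class = "ring_width")
}

#' Measure a synthetic scene end to end
#'
#' Runs the fluorescence-morphometry pipeline on a [make_scene()] /
#' [scene_with_gap()] bundle exactly as it would run on real data, using only
#' the scene's images and auto-emitted ROIs (never the truth record):
#' membrane diameter from two perpendicular line scans, membrane void area
#' from the torus threshold, PCM area and intensity from the
#' background-sum threshold, and the gap statistic.
#'
#' @param scene output of [make_scene()] or [scene_with_gap()].
#' @param scan_length,line_width line-scan geometry (defaults: image extent
#'   minus margin; single-pixel width).
#' @return list with `diameter` (a `diameter_measurement`), `void_area`,
#'   `pcm` (an `area_intensity`), and `gap` (a [gap_area()]).
#' @export
measure_scene <- function(scene, scan_length = NULL, line_width = NULL) {
  memb <- scene$channels$centriculum
  center <- scene$truth$center
  if (is.null(scan_length))
    scan_length <- (min(dim(memb$pixels)) - 4) * memb$pixel_size
  if (is.null(line_width)) line_width <- memb$pixel_size
  p1 <- line_scan(memb, center, 0, scan_length, line_width)
  p2 <- line_scan(memb, center, 90, scan_length, line_width)
  diam <- diameter_from_profiles(p1, p2)
  tm <- torus_threshold(memb, scene$rois$torus_outer, scene$rois$torus_inner)
  v_area <- void_area(tm, center)
  pcm <- area_intensity(pcm_threshold(scene$channels$pcm, scene$rois$background),
                        scene$channels$pcm)
  list(diameter = diam, void_area = v_area, pcm = pcm,
       gap = gap_area(v_area, pcm$area))
}
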